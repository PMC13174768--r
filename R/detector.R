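#' Idealized cylindrical PET ring
#'
#' Crystals are perfect absorbers at their front face on a cylinder of the
#' given radius (axis along z). Photons are projected from their last origin
#' along their direction to the ring intersection, accepted with a fixed
#' per-photon efficiency inside the axial extent, and recorded with
#' Gaussian-blurred energy and time at the nearest crystal center.
#'
#' @param radius_mm Ring radius in mm.
#' @param axial_mm Axial length in mm.
#' @param pitch_mm Crystal pitch in mm (transaxial and axial).
#' @param energy_res_fwhm Fractional energy resolution (FWHM) at 511 keV.
#' @param energy_window_kev Two-element keV acceptance window.
#' @param tau_ns Coincidence time window in ns.
#' @param timing_fwhm_ps Coincidence timing resolution FWHM in ps (0 = no
#'   blur, non-TOF).
#' @param efficiency Detection probability per incident photon.
#' @param preset `"clinical"` (radius 410 mm, 3.2 mm pitch, 214 ps TOF) or
#'   `"preclinical"` (radius 80 mm, 1.12 mm pitch, no TOF); explicit
#'   arguments override preset values.
#' @return A `ppt_ring`.
#' @export
#' @examples
#' detector_ring("clinical")
detector_ring <- function(preset = NULL, radius_mm = NULL, axial_mm = NULL,
                          pitch_mm = NULL, energy_res_fwhm = 0.11,
                          energy_window_kev = c(435, 585), tau_ns = 4,
                          timing_fwhm_ps = NULL, efficiency = 1) {
  def <- list(radius_mm = 410, axial_mm = 260, pitch_mm = 3.2,
              timing_fwhm_ps = 214)
  if (!is.null(preset)) {
    def <- switch(match.arg(preset, c("clinical", "preclinical")),
      clinical = list(radius_mm = 410, axial_mm = 260, pitch_mm = 3.2,
                      timing_fwhm_ps = 214),
      preclinical = list(radius_mm = 80, axial_mm = 100, pitch_mm = 1.12,
                         timing_fwhm_ps = 0))
  }
  if (is.null(radius_mm)) radius_mm <- def$radius_mm
  if (is.null(axial_mm)) axial_mm <- def$axial_mm
  if (is.null(pitch_mm)) pitch_mm <- def$pitch_mm
  if (is.null(timing_fwhm_ps)) timing_fwhm_ps <- def$timing_fwhm_ps
  stopifnot(radius_mm > 0, axial_mm > 0, pitch_mm > 0, tau_ns > 0,
            efficiency >= 0, efficiency <= 1,
            length(energy_window_kev) == 2,
            energy_window_kev[1] < energy_window_kev[2])
  n_phi <- max(8L, as.integer(round(2 * pi * radius_mm / pitch_mm)))
  n_z <- max(1L, as.integer(round(axial_mm / pitch_mm)))
  structure(list(
    radius_mm = radius_mm, axial_mm = axial_mm, pitch_mm = pitch_mm,
    n_phi = n_phi, n_z = n_z,
    energy_res_fwhm = energy_res_fwhm,
    energy_window_kev = energy_window_kev,
    tau_ns = tau_ns, timing_fwhm_ps = timing_fwhm_ps,
    efficiency = efficiency), class = "ppt_ring")
}

#' @export
print.ppt_ring <- function(x, ...) {
  cat(sprintf(
    "<ppt_ring> radius %g mm, axial %g mm, %d x %d crystals (%g mm pitch), TOF %g ps\n",
    x$radius_mm, x$axial_mm, x$n_phi, x$n_z, x$pitch_mm, x$timing_fwhm_ps))
  invisible(x)
}

# crystal center for (iphi, iz)
.ppt_crystal_center <- function(ring, iphi, iz) {
  phi <- (iphi - 0.5) / ring$n_phi * 2 * pi
  z <- -ring$axial_mm / 2 + (iz - 0.5) * (ring$axial_mm / ring$n_z)
  cbind(ring$radius_mm * cos(phi), ring$radius_mm * sin(phi), z)
}

#' Project photons onto the detector ring
#'
#' @param photons A data frame of escaping photons with origin `x`, `y`,
#'   `z` (mm), direction `dx`, `dy`, `dz`, `energy` (MeV), `time` (ns) and
#'   (optionally) `history`.
#' @param ring A [detector_ring()].
#' @return A tibble of singles: `history`, crystal indices `iphi`, `iz`,
#'   hit position `hx`, `hy`, `hz` (crystal center, mm), blurred `energy_kev`
#'   and `time` (ns). Photons whose origin lies outside the bore are skipped
#'   and counted in the `n_outside_bore` attribute; photons that miss the
#'   axial extent are dropped.
#' @export
detect_singles <- function(photons, ring) {
  stopifnot(inherits(ring, "ppt_ring"))
  n <- nrow(photons)
  if (!n) {
    return(structure(tibble::tibble(
      history = integer(), iphi = integer(), iz = integer(), hx = numeric(),
      hy = numeric(), hz = numeric(), energy_kev = numeric(),
      time = numeric()), n_outside_bore = 0L))
  }
  ox <- photons$x; oy <- photons$y; oz <- photons$z
  dx <- photons$dx; dy <- photons$dy; dz <- photons$dz
  inside <- ox^2 + oy^2 < ring$radius_mm^2
  n_out <- sum(!inside)
  # forward intersection with the cylinder x^2 + y^2 = R^2
  a <- dx^2 + dy^2
  b <- 2 * (ox * dx + oy * dy)
  cc <- ox^2 + oy^2 - ring$radius_mm^2
  disc <- b^2 - 4 * a * cc
  t <- rep(NA_real_, n)
  okq <- inside & a > 1e-12 & disc > 0
  t[okq] <- (-b[okq] + sqrt(disc[okq])) / (2 * a[okq])
  hz <- oz + dz * t
  hit <- okq & !is.na(t) & t > 0 & abs(hz) <= ring$axial_mm / 2
  hit[hit] <- hit[hit] & stats::runif(sum(hit)) < ring$efficiency
  idx <- which(hit)
  if (!length(idx)) {
    return(structure(tibble::tibble(
      history = integer(), iphi = integer(), iz = integer(), hx = numeric(),
      hy = numeric(), hz = numeric(), energy_kev = numeric(),
      time = numeric()), n_outside_bore = n_out))
  }
  hx <- ox[idx] + dx[idx] * t[idx]
  hy <- oy[idx] + dy[idx] * t[idx]
  hzz <- hz[idx]
  phi <- atan2(hy, hx) %% (2 * pi)
  iphi <- pmin(ring$n_phi, 1L + as.integer(floor(phi / (2 * pi) * ring$n_phi)))
  iz <- pmin(ring$n_z, pmax(1L, 1L + as.integer(
    floor((hzz + ring$axial_mm / 2) / (ring$axial_mm / ring$n_z)))))
  cen <- .ppt_crystal_center(ring, iphi, iz)
  flight <- t[idx] / .ppt_c_mm_ns
  sd_e <- ring$energy_res_fwhm * 511 / (2 * sqrt(2 * log(2)))
  sd_t <- ring$timing_fwhm_ps / 1000 / (2 * sqrt(2 * log(2))) / sqrt(2)
  e_blur <- photons$energy[idx] * 1000 +
    if (sd_e > 0) stats::rnorm(length(idx), 0, sd_e) else 0
  t_blur <- photons$time[idx] + flight +
    if (sd_t > 0) stats::rnorm(length(idx), 0, sd_t) else 0
  hist <- if ("history" %in% names(photons)) photons$history[idx] else idx
  structure(tibble::tibble(
    history = hist, iphi = iphi, iz = iz,
    hx = cen[, 1], hy = cen[, 2], hz = cen[, 3],
    energy_kev = e_blur, time = t_blur), n_outside_bore = n_out)
}

#' Sort singles into coincidences
#'
#' Applies the energy window to the singles, then forms prompt pairs whose
#' time difference lies within the coincidence window; windows containing
#' more than two in-window hits are discarded. The activity timeline is
#' per-history (each decay is an isolated time frame), so random
#' coincidences between unrelated decays are not formed.
#'
#' @param hits Singles from [detect_singles()].
#' @param ring A [detector_ring()].
#' @return A `ppt_coincidences` tibble: crystal indices `iphi1`, `iz1`,
#'   `iphi2`, `iz2`, hit positions `x1`, `y1`, `z1`, `x2`, `y2`, `z2`,
#'   energies `e1_kev`, `e2_kev`, `dt_ns` (= t1 - t2) and `history`.
#' @export
sort_coincidences <- function(hits, ring) {
  stopifnot(inherits(ring, "ppt_ring"))
  win <- ring$energy_window_kev
  h <- dplyr::filter(hits, .data$energy_kev >= win[1],
                     .data$energy_kev <= win[2])
  empty <- tibble::tibble(
    history = integer(), iphi1 = integer(), iz1 = integer(),
    iphi2 = integer(), iz2 = integer(), x1 = numeric(), y1 = numeric(),
    z1 = numeric(), x2 = numeric(), y2 = numeric(), z2 = numeric(),
    e1_kev = numeric(), e2_kev = numeric(), dt_ns = numeric())
  if (nrow(h) < 2) return(structure(empty, ring = ring,
                                    class = c("ppt_coincidences",
                                              class(empty))))
  h <- dplyr::arrange(h, .data$history, .data$time)
  counts <- table(h$history)
  doubles <- as.integer(names(counts)[counts == 2])
  h2 <- h[h$history %in% doubles, ]
  if (!nrow(h2)) return(structure(empty, ring = ring,
                                  class = c("ppt_coincidences",
                                            class(empty))))
  i1 <- seq(1, nrow(h2), by = 2); i2 <- i1 + 1
  dt <- h2$time[i1] - h2$time[i2]
  ok <- abs(dt) <= ring$tau_ns
  out <- tibble::tibble(
    history = h2$history[i1][ok],
    iphi1 = h2$iphi[i1][ok], iz1 = h2$iz[i1][ok],
    iphi2 = h2$iphi[i2][ok], iz2 = h2$iz[i2][ok],
    x1 = h2$hx[i1][ok], y1 = h2$hy[i1][ok], z1 = h2$hz[i1][ok],
    x2 = h2$hx[i2][ok], y2 = h2$hy[i2][ok], z2 = h2$hz[i2][ok],
    e1_kev = h2$energy_kev[i1][ok], e2_kev = h2$energy_kev[i2][ok],
    dt_ns = dt[ok])
  structure(out, ring = ring, class = c("ppt_coincidences", class(out)))
}

#' Write a coincidence list as a list-mode text file
#'
#' Columnar tab-separated list-mode output; a commented header records the
#' ring geometry.
#'
#' @param coincidences A `ppt_coincidences` tibble.
#' @param ring The [detector_ring()] used.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_listmode <- function(coincidences, ring, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# pptsim list-mode: radius_mm=%g axial_mm=%g pitch_mm=%g tau_ns=%g timing_fwhm_ps=%g window_kev=%g-%g",
    ring$radius_mm, ring$axial_mm, ring$pitch_mm, ring$tau_ns,
    ring$timing_fwhm_ps, ring$energy_window_kev[1],
    ring$energy_window_kev[2]), con)
  utils::write.table(as.data.frame(coincidences), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                             comment.char = "#"))
  structure(out, class = c("ppt_coincidences", class(out)))
}
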