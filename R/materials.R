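#' @title Embedded material data: photon attenuation and positron stopping
#'
#' @description
#' Six tissue-equivalent materials (water, adipose, inflated lung, brain,
#' cortical bone, air) carry per-channel linear attenuation coefficients
#' (photoelectric, Compton, pair production) on a fixed photon-energy grid
#' spanning 0.05--3 MeV, plus positron CSDA range tables. The Compton channel
#' derives from the Klein--Nishina cross section times the material electron
#' density; pair production is an XCOM-style compilation for water scaled by
#' density and mean Z^2/A; the photoelectric channel is a parametrized
#' power-law fit (it is negligible above a few hundred keV, which is the
#' regime this simulator works in). Coefficients exclude coherent (Rayleigh)
#' scattering throughout.
#'
#' @name pptsim-materials
NULL

# water positron/electron CSDA range table (ESTAR-style), MeV -> g/cm^2
.ppt_csda_ke <- c(0.01, 0.025, 0.05, 0.075, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5,
                  0.6, 0.7, 0.8, 1.0, 1.25, 1.5, 1.75, 2.0)
.ppt_csda_water <- c(2.52e-4, 1.27e-3, 4.32e-3, 8.89e-3, 1.431e-2, 2.82e-2,
                     4.50e-2, 8.42e-2, 1.28e-1, 1.77e-1, 2.28e-1, 2.76e-1,
                     3.30e-1, 4.37e-1, 5.68e-1, 7.08e-1, 8.46e-1, 9.79e-1)
# dedicated cortical-bone mass range (g/cm^2): water values scaled by the
# stopping-power ratio (Z/A)_water / (Z/A)_bone = 1.078
.ppt_csda_bone <- .ppt_csda_water * 1.078

.ppt_registry <- new.env(parent = emptyenv())

.ppt_builtin_material <- function(name) {
  d <- .ppt_material_data[[name]]
  za_factor <- .ppt_material_data$water$z_over_a / d$z_over_a
  csda_mass <- if (name == "bone") .ppt_csda_bone else .ppt_csda_water * za_factor
  structure(
    list(
      name = name,
      density = d$density,
      energies = .ppt_energy_grid,
      mu_pe = d$mu_pe,
      mu_compton = d$mu_compton,
      mu_pair = d$mu_pair,
      x0_cm = d$x0_mass / d$density,
      z_over_a = d$z_over_a,
      csda_ke = .ppt_csda_ke,
      csda_cm = csda_mass / d$density
    ),
    class = "ppt_material"
  )
}

.ppt_get_registry <- function() {
  if (!length(ls(.ppt_registry))) {
    for (nm in names(.ppt_material_data)) {
      assign(nm, .ppt_builtin_material(nm), envir = .ppt_registry)
    }
  }
  .ppt_registry
}

#' List registered materials
#'
#' @return A tibble with one row per registered material: name, density
#'   (g/cm^3), mean Z/A, and the total linear attenuation coefficient at
#'   0.511 and 2.617 MeV (cm^-1).
#' @export
#' @examples
#' ppt_materials()
ppt_materials <- function() {
  reg <- .ppt_get_registry()
  nms <- sort(ls(reg))
  tibble::tibble(
    material = nms,
    density = vapply(nms, function(n) get(n, envir = reg)$density, 0),
    z_over_a = vapply(nms, function(n) get(n, envir = reg)$z_over_a, 0),
    mu_511 = vapply(nms, function(n) mu_total(n, 0.511), 0),
    mu_2617 = vapply(nms, function(n) mu_total(n, 2.617), 0)
  )
}

#' Retrieve a material definition
#'
#' @param material A material name (see [ppt_materials()]) or a
#'   `ppt_material` object, returned unchanged.
#' @return A `ppt_material` object.
#' @export
ppt_material <- function(material) {
  if (inherits(material, "ppt_material")) return(material)
  reg <- .ppt_get_registry()
  if (!is.character(material) || length(material) != 1 || !exists(material, envir = reg)) {
    stop("unknown material '", material, "'; registered: ",
         paste(sort(ls(reg)), collapse = ", "), call. = FALSE)
  }
  get(material, envir = reg)
}

#' Register a user-supplied material
#'
#' Adds (or replaces) a material in the session registry from explicit
#' coefficient tables. Tables must be strictly increasing in energy and
#' nonnegative; the pair-production channel must vanish below the 1.022 MeV
#' threshold.
#'
#' @param name Material label.
#' @param density Mass density in g/cm^3.
#' @param energies Photon energy grid in MeV (strictly increasing).
#' @param mu_pe,mu_compton,mu_pair Linear attenuation coefficients (cm^-1)
#'   per channel on `energies`.
#' @param csda_ke,csda_cm Positron kinetic-energy grid (MeV) and CSDA range
#'   (cm) table.
#' @param x0_cm Radiation length in cm (used for multiple scattering).
#' @return The registered `ppt_material`, invisibly.
#' @export
register_material <- function(name, density, energies, mu_pe, mu_compton,
                              mu_pair, csda_ke, csda_cm, x0_cm) {
  stopifnot(length(energies) >= 2, all(diff(energies) > 0),
            length(mu_pe) == length(energies),
            length(mu_compton) == length(energies),
            length(mu_pair) == length(energies),
            all(mu_pe >= 0), all(mu_compton >= 0), all(mu_pair >= 0),
            all(diff(csda_ke) > 0), length(csda_ke) == length(csda_cm),
            all(csda_cm >= 0), density > 0, x0_cm > 0)
  if (any(mu_pair[energies < 1.022] > 0)) {
    stop("pair-production coefficient must be 0 below 1.022 MeV", call. = FALSE)
  }
  mat <- structure(
    list(name = name, density = density, energies = energies, mu_pe = mu_pe,
         mu_compton = mu_compton, mu_pair = mu_pair, x0_cm = x0_cm,
         z_over_a = NA_real_, csda_ke = csda_ke, csda_cm = csda_cm),
    class = "ppt_material"
  )
  assign(name, mat, envir = .ppt_get_registry())
  invisible(mat)
}

#' @export
print.ppt_material <- function(x, ...) {
  cat(sprintf("<ppt_material> %s  (rho = %g g/cm^3, %d grid energies %g-%g MeV)\n",
              x$name, x$density, length(x$energies), min(x$energies),
              max(x$energies)))
  invisible(x)
}

# log-log interpolation of one channel; zeros below/at threshold are kept at
# zero, with a linear ramp between the last zero node and the first positive
# node so that values at grid points are reproduced exactly
.ppt_interp_channel <- function(energies, mu, e) {
  out <- numeric(length(e))
  pos <- mu > 0
  if (!any(pos)) return(out)
  i0 <- which(pos)[1]
  if (i0 > 1) {
    ramp <- e >= energies[i0 - 1] & e < energies[i0]
    out[ramp] <- mu[i0] * (e[ramp] - energies[i0 - 1]) /
      (energies[i0] - energies[i0 - 1])
  }
  hi <- e >= energies[i0]
  if (any(hi)) {
    out[hi] <- exp(stats::approx(log(energies[pos]), log(mu[pos]),
                                 xout = log(e[hi]), rule = 2)$y)
  }
  out
}

.ppt_check_energy <- function(mat, energy) {
  lo <- min(mat$energies); hi <- max(mat$energies)
  if (any(energy < lo | energy > hi)) {
    stop(sprintf("photon energy outside tabulated range [%g, %g] MeV", lo, hi),
         call. = FALSE)
  }
}

#' Per-channel linear attenuation coefficients
#'
#' Interpolates the embedded tables log-log in energy. The pair-production
#' channel is exactly zero below the 1.022 MeV threshold.
#'
#' @param material Material name or `ppt_material`.
#' @param energy Photon energy in MeV (vectorized); must lie inside the
#'   tabulated range.
#' @return A tibble with columns `energy`, `photoelectric`, `compton`,
#'   `pair`, and `total` (all cm^-1).
#' @export
#' @examples
#' get_coefficients("water", 2.617)
get_coefficients <- function(material, energy) {
  mat <- ppt_material(material)
  .ppt_check_energy(mat, energy)
  pe <- .ppt_interp_channel(mat$energies, mat$mu_pe, energy)
  co <- .ppt_interp_channel(mat$energies, mat$mu_compton, energy)
  pp <- .ppt_interp_channel(mat$energies, mat$mu_pair, energy)
  pp[energy < 1.022] <- 0
  tibble::tibble(energy = energy, photoelectric = pe, compton = co,
                 pair = pp, total = pe + co + pp)
}

#' Total linear attenuation coefficient (cm^-1)
#'
#' @inheritParams get_coefficients
#' @return Numeric vector of total coefficients.
#' @export
mu_total <- function(material, energy) {
  get_coefficients(material, energy)$total
}

#' Photon mean free path (cm)
#'
#' @inheritParams get_coefficients
#' @return `1 / mu_total(material, energy)` in cm.
#' @export
#' @examples
#' mean_free_path("water", 2.617) # about 23.4 cm
mean_free_path <- function(material, energy) {
  1 / mu_total(material, energy)
}

#' Positron CSDA range (cm)
#'
#' Continuous-slowing-down-approximation path length for a positron of the
#' given kinetic energy; linear interpolation of the embedded range table,
#' zero at zero energy.
#'
#' @param material Material name or `ppt_material`.
#' @param ke Positron kinetic energy in MeV (vectorized, nonnegative).
#' @return CSDA range in cm.
#' @export
#' @examples
#' csda_range("water", 1.56) # about 0.7 cm
csda_range <- function(material, ke) {
  if (any(ke < 0)) stop("kinetic energy must be nonnegative", call. = FALSE)
  mat <- ppt_material(material)
  stats::approx(c(0, mat$csda_ke), c(0, mat$csda_cm), xout = ke, rule = 2)$y
}

# inverse lookup: remaining range (cm) -> kinetic energy (MeV)
.ppt_ke_from_range <- function(mat, range_cm) {
  stats::approx(c(0, mat$csda_cm), c(0, mat$csda_ke),
                xout = pmax(range_cm, 0), rule = 2)$y
}

#' Decay-chain emission spectrum
#'
#' The gamma lines relevant to imaging a Pb-212 in-vivo generator, expressed
#' as intensities per parent Pb-212 decay. The 2.617 MeV line of the Tl-208
#' daughter (emitted with ~99% probability per Tl-208 decay, reached in 36%
#' of Pb-212 decays) is the signal line for pair production tomography; the
#' 239 keV Pb-212 line falls outside a 511 keV PET energy window.
#'
#' @return A tibble with columns `energy` (MeV), `intensity` (per parent
#'   decay, in `[0, 1]`) and `nuclide`.
#' @export
#' @examples
#' emission_spectrum()
emission_spectrum <- function() {
  tibble::tibble(
    energy = c(0.0787, 0.2386, 0.3001, 0.5832, 0.7274, 0.8605, 2.617),
    intensity = c(0.177, 0.436, 0.033, 0.306, 0.0667, 0.0450, 0.36),
    nuclide = c("Pb-212", "Pb-212", "Pb-212", "Tl-208", "Bi-212", "Tl-208",
                "Tl-208")
  )
}

#' Write or read materials and spectra as structured text
#'
#' Materials and emission spectra round-trip through YAML so that a run
#' configuration can override the embedded data.
#'
#' @param material A `ppt_material`.
#' @param path File path.
#' @return `write_material()` returns `path` invisibly; `read_material()`
#'   returns (and registers) the `ppt_material`.
#' @export
write_material <- function(material, path) {
  mat <- ppt_material(material)
  yaml::write_yaml(unclass(mat), path)
  invisible(path)
}

#' @rdname write_material
#' @export
read_material <- function(path) {
  d <- yaml::read_yaml(path)
  register_material(d$name, d$density, as.numeric(d$energies),
                    as.numeric(d$mu_pe), as.numeric(d$mu_compton),
                    as.numeric(d$mu_pair), as.numeric(d$csda_ke),
                    as.numeric(d$csda_cm), d$x0_cm)
}
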