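#' Summary statistics for PPT simulations
#'
#' Slice/projection profiles of event coordinates, a Lorentzian-plus-
#' exponential profile model with FWHM, positron kinetic-energy and range
#' statistics, first-interaction channel budgets with an analytic
#' cross-check, and the central-cube pair-production efficiency metric used
#' to compare materials.
#'
#' @name pptsim-analysis
NULL

#' Histogram a coordinate of event positions
#'
#' In slice mode only events inside a central slab on the two other axes
#' are counted (half-thickness per axis); in projection mode all events are
#' aggregated, which broadens the displayed profile.
#'
#' @param events A data frame with columns `x`, `y`, `z` (mm), e.g.
#'   `log$pairs` or `log$annihilations`.
#' @param coord Coordinate to histogram: `"x"`, `"y"` or `"z"`.
#' @param half_thickness_mm Slab half-thickness on the other two axes
#'   (slice mode; default 1 mm).
#' @param bin_mm Bin width in mm (default 0.25).
#' @param mode `"slice"` or `"projection"`.
#' @param range_mm Half-range of the histogram (default: data extent).
#' @param normalize Peak-normalize the counts.
#' @return A `ppt_profile` tibble with `x` (bin centers, mm), `counts` and
#'   `value` (normalized when requested); binning metadata in attributes.
#' @export
slice_profile <- function(events, coord = "x", half_thickness_mm = 1,
                          bin_mm = 0.25, mode = c("slice", "projection"),
                          range_mm = NULL, normalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(coord %in% c("x", "y", "z"))
  if (!nrow(events)) stop("no events to profile", call. = FALSE)
  v <- events[[coord]]
  if (mode == "slice") {
    others <- setdiff(c("x", "y", "z"), coord)
    keep <- abs(events[[others[1]]]) <= half_thickness_mm &
      abs(events[[others[2]]]) <= half_thickness_mm
    v <- v[keep]
    if (!length(v)) {
      stop("no events inside the slice slab; consider mode = \"projection\"",
           call. = FALSE)
    }
  }
  if (is.null(range_mm)) range_mm <- max(abs(v)) + bin_mm
  nb <- ceiling(range_mm / bin_mm)
  edges <- seq(-nb * bin_mm, nb * bin_mm, by = bin_mm)
  ct <- as.numeric(table(cut(v, edges, include.lowest = TRUE)))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  val <- if (normalize && max(ct) > 0) ct / max(ct) else ct
  structure(tibble::tibble(x = centers, counts = ct, value = val),
            bin_mm = bin_mm, mode = mode, coord = coord,
            half_thickness_mm = half_thickness_mm,
            n_events = length(v), normalized = normalize,
            class = c("ppt_profile", class(tibble::tibble())))
}

# FWHM of a sampled curve by linear interpolation of half-max crossings
.ppt_numeric_fwhm <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  left <- right <- NA_real_
  for (i in seq(pk, 2)) {
    if (y[i - 1] < half) {
      left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
      break
    }
  }
  for (i in seq(pk, length(y) - 1)) {
    if (y[i + 1] < half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
      break
    }
  }
  right - left
}

#' Fit a Lorentzian-plus-exponential profile model
#'
#' Nonlinear least squares of
#' `f(x) = A / (1 + (x/sigma)^2) + B * exp(-C * |x|)`
#' to a (normalized) profile. The reported `fwhm` is `2 * sigma`, the full
#' width at half maximum of the Lorentzian component (the exponential term
#' is a broad background); the numeric FWHM of the total fitted curve is
#' also reported for transparency. Starting values come from the raw
#' histogram moments: `sigma0` = half the raw half-max width, `A0` = peak
#' height, `B0` = 10% of peak, `C0 = 1/(5 sigma0)`.
#'
#' @param profile A `ppt_profile` from [slice_profile()] (at least 10
#'   occupied bins).
#' @param fixed Optional named list of parameters to hold at a fixed value
#'   (e.g. `list(A = 0)` to fit a pure exponential background).
#' @return A `ppt_profile_fit` with elements `A`, `sigma`, `B`, `C`,
#'   `fwhm` (mm), `fwhm_total` (mm), `rss`, `r_squared`, `fit` (the nls
#'   object) and the input profile.
#' @export
fit_profile <- function(profile, fixed = NULL) {
  occ <- sum(profile$counts > 0)
  if (occ < 10) {
    stop("need at least 10 occupied bins (got ", occ, ")", call. = FALSE)
  }
  y <- profile$value
  if (max(y) <= min(y)) stop("degenerate flat profile", call. = FALSE)
  x <- profile$x
  a0 <- max(y)
  raw_fwhm <- .ppt_numeric_fwhm(x, y)
  if (!is.finite(raw_fwhm) || raw_fwhm <= 0) raw_fwhm <- 2 * attr(profile, "bin_mm")
  s0 <- raw_fwhm / 2
  start <- c(A = a0, sigma = s0, B = 0.1 * a0, C = 1 / (5 * s0))
  model <- function(p, xx) {
    p[["A"]] / (1 + (xx / p[["sigma"]])^2) +
      p[["B"]] * exp(-p[["C"]] * abs(xx))
  }
  # Poisson-weighted (chi-square) residuals on the normalized scale; empty
  # bins get unit counts so they still constrain the background
  w <- if (all(profile$counts == round(profile$counts)) &&
             max(profile$counts) > 0) {
    max(profile$counts) / sqrt(pmax(profile$counts, 1))
  } else rep(1, length(y))
  w <- w / mean(w)
  free <- setdiff(names(start), names(fixed))
  full_par <- function(p) {
    out <- as.list(p)
    out[names(fixed)] <- fixed
    out
  }
  lower <- c(A = 0, sigma = 1e-6, B = 0, C = 1e-6)
  fit <- minpack.lm::nls.lm(
    par = start[free], lower = lower[free],
    fn = function(p) (y - model(full_par(p), x)) * w,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000))
  if (!fit$info %in% 1:4) {
    stop("profile fit did not converge (info ", fit$info, "; last A=",
         signif(fit$par[["A"]], 3), ", sigma=", signif(fit$par[["sigma"]], 3),
         ", B=", signif(fit$par[["B"]], 3), ", C=", signif(fit$par[["C"]], 3),
         "): ", fit$message, call. = FALSE)
  }
  cf <- unlist(full_par(fit$par))
  xf <- seq(min(x), max(x), length.out = 4001)
  yf <- model(cf, xf)
  rss <- sum((y - model(full_par(fit$par), x))^2)
  structure(list(
    A = cf[["A"]], sigma = cf[["sigma"]], B = cf[["B"]], C = cf[["C"]],
    fwhm = 2 * cf[["sigma"]],
    fwhm_total = .ppt_numeric_fwhm(xf, yf),
    rss = rss,
    r_squared = 1 - rss / sum((y - mean(y))^2),
    n_bins = length(x), fit = fit, profile = profile),
    class = "ppt_profile_fit")
}

#' @export
print.ppt_profile_fit <- function(x, ...) {
  cat(sprintf(
    "<ppt_profile_fit> A=%.3g sigma=%.3g mm B=%.3g C=%.3g /mm | FWHM (Lorentzian) = %.3g mm, FWHM (total) = %.3g mm, R^2 = %.4f\n",
    x$A, x$sigma, x$B, x$C, x$fwhm, x$fwhm_total, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy profile-fit parameters
#'
#' @param x A `ppt_profile_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @method tidy ppt_profile_fit
#' @export
tidy.ppt_profile_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' One-row fit summary
#'
#' @param x A `ppt_profile_fit`.
#' @param ... Unused.
#' @return A tibble with `fwhm`, `fwhm_total`, `rss`, `r_squared`, `n_bins`.
#' @method glance ppt_profile_fit
#' @export
glance.ppt_profile_fit <- function(x, ...) {
  tibble::tibble(fwhm = x$fwhm, fwhm_total = x$fwhm_total, rss = x$rss,
                 r_squared = x$r_squared, n_bins = x$n_bins)
}

#' Positron kinetic-energy and range statistics
#'
#' @param log A `ppt_eventlog` with at least 100 pair events.
#' @return A list with `mean_ke` (MeV, positron), `ke_center` (MeV,
#'   symmetry center estimate `(mean T+ + mean T-)/2`), `mean_range` (mm),
#'   and `percentiles` (tibble of the 50/90/99/99.9th percentiles of
#'   `|r_a - r_p|`). The 99.9th percentile operationalizes the range
#'   end-point.
#' @export
positron_stats <- function(log) {
  if (nrow(log$pairs) < 100) {
    stop("need at least 100 pair events (got ", nrow(log$pairs), ")",
         call. = FALSE)
  }
  rng <- log$annihilations$range
  q <- stats::quantile(rng, c(0.5, 0.9, 0.99, 0.999), names = FALSE)
  list(
    mean_ke = mean(log$pairs$t_plus),
    ke_center = (mean(log$pairs$t_plus) + mean(log$pairs$t_minus)) / 2,
    mean_range = mean(rng),
    percentiles = tibble::tibble(percentile = c(50, 90, 99, 99.9),
                                 range_mm = q)
  )
}

#' First-interaction channel fractions
#'
#' Fractions over primaries of histories whose first interaction inside the
#' grid was each channel (or none); sums to 1 exactly.
#'
#' @param log A `ppt_eventlog`.
#' @return A tibble with `channel` and `fraction`.
#' @export
interaction_fractions <- function(log) {
  n <- log$n_primaries
  cnt <- tabulate(log$first_channel + 1L, nbins = 4L)
  tibble::tibble(
    channel = c("none", "photoelectric", "compton", "pair"),
    fraction = if (n > 0) cnt / n else rep(0, 4)
  )
}

#' Analytic first-interaction oracle for a centered point source in a
#' homogeneous cube
#'
#' Integrates `1 - exp(-mu * s(Omega))` over directions (s = distance from
#' the center to the cube surface) and splits channels by `mu_i/mu_total`.
#' Used as an independent cross-check of the Monte Carlo budget.
#'
#' @param material Material name or `ppt_material`.
#' @param energy Photon energy in MeV.
#' @param side_cm Cube side in cm.
#' @param n_dirs Number of integration directions.
#' @return A tibble with `channel` and `fraction`.
#' @export
interaction_fractions_oracle <- function(material, energy, side_cm,
                                         n_dirs = 1e4) {
  cf <- get_coefficients(material, energy)
  # deterministic spherical Fibonacci direction set
  i <- seq_len(n_dirs)
  z <- 1 - (2 * i - 1) / n_dirs
  phi <- i * pi * (3 - sqrt(5))
  st <- sqrt(pmax(0, 1 - z^2))
  w <- cbind(st * cos(phi), st * sin(phi), z)
  s <- (side_cm / 2) / pmax(abs(w[, 1]), abs(w[, 2]), abs(w[, 3]))
  p_int <- mean(1 - exp(-cf$total * s))
  tibble::tibble(
    channel = c("none", "photoelectric", "compton", "pair"),
    fraction = c(1 - p_int,
                 p_int * cf$photoelectric / cf$total,
                 p_int * cf$compton / cf$total,
                 p_int * cf$pair / cf$total)
  )
}

#' Pair-production efficiency in a centered cube
#'
#' The number of pair-production (and annihilation) events inside a
#' centered cube region of interest, per primary photon: the signal a small
#' "voxel" around the source would collect.
#'
#' @param log A `ppt_eventlog`.
#' @param roi_mm Side length of the centered cubic ROI in mm (default 10).
#' @return A tibble with `production_efficiency` and
#'   `annihilation_efficiency` (events per primary) plus the raw counts.
#' @export
pair_efficiency <- function(log, roi_mm = 10) {
  half <- roi_mm / 2
  extent <- log$grid_shape * log$voxel_mm
  if (any(roi_mm > extent)) {
    stop("ROI larger than the phantom extent", call. = FALSE)
  }
  inroi <- function(d) sum(abs(d$x) <= half & abs(d$y) <= half &
                             abs(d$z) <= half)
  np <- inroi(log$pairs)
  na <- inroi(log$annihilations)
  tibble::tibble(
    n_production = np, n_annihilation = na,
    production_efficiency = np / log$n_primaries,
    annihilation_efficiency = na / log$n_primaries
  )
}

#' Compare pair efficiencies across material runs
#'
#' @param logs A named list of `ppt_eventlog`s (names = material labels).
#' @param roi_mm ROI side in mm.
#' @return A tibble with one row per material and the efficiency ratio
#'   relative to the last-named material.
#' @export
efficiency_table <- function(logs, roi_mm = 10) {
  rows <- lapply(names(logs), function(nm) {
    dplyr::mutate(pair_efficiency(logs[[nm]], roi_mm), material = nm,
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}
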