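#' Monte Carlo photon and positron transport
#'
#' Photons are tracked through the voxel grid by Woodcock delta-tracking
#' against the majorant total attenuation of the materials present.
#' Interaction channels (photoelectric, Compton, pair production) are
#' sampled proportionally to the local per-channel coefficients. Compton
#' scattering follows the Klein--Nishina differential cross section; pair
#' production shares the available kinetic energy between the electron and
#' positron with a symmetric Bethe--Heitler-shaped (or flat) distribution.
#' Positrons are transported by a condensed-history random walk over steps
#' of equal CSDA-path fraction with Gaussian multiple-scattering deflections
#' (Rossi--Greisen scattering constant Es = 21.2 MeV), and annihilate at
#' rest into two back-to-back 511 keV photons.
#'
#' @name pptsim-transport
NULL

.ppt_c_mm_ns <- 299.792458  # speed of light

# isotropic unit vectors, n x 3
.ppt_iso_dirs <- function(n) {
  u <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - u^2))
  cbind(st * cos(ph), st * sin(ph), u)
}

# rotate unit vectors `dir` by polar angle theta (rad) about a uniform or
# given azimuth
.ppt_rotate_dirs <- function(dir, theta, phi = stats::runif(nrow(dir), 0, 2 * pi)) {
  ct <- cos(theta); st <- sin(theta)
  pick <- abs(dir[, 3]) < 0.9
  ref <- cbind(ifelse(pick, 0, 1), 0, ifelse(pick, 1, 0))
  e1 <- cbind(dir[, 2] * ref[, 3] - dir[, 3] * ref[, 2],
              dir[, 3] * ref[, 1] - dir[, 1] * ref[, 3],
              dir[, 1] * ref[, 2] - dir[, 2] * ref[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(dir[, 2] * e1[, 3] - dir[, 3] * e1[, 2],
              dir[, 3] * e1[, 1] - dir[, 1] * e1[, 3],
              dir[, 1] * e1[, 2] - dir[, 2] * e1[, 1])
  out <- dir * ct + e1 * (st * cos(phi)) + e2 * (st * sin(phi))
  out / sqrt(rowSums(out^2))
}

# per-photon channel coefficients (cm^-1) for material ids in a grid
.ppt_local_mu <- function(mats, matid, energy) {
  n <- length(matid)
  pe <- co <- pp <- numeric(n)
  for (m in unique(matid)) {
    if (m == 0) next
    sel <- matid == m
    cf <- get_coefficients(mats[[m]], energy[sel])
    pe[sel] <- cf$photoelectric; co[sel] <- cf$compton; pp[sel] <- cf$pair
  }
  list(pe = pe, compton = co, pair = pp, total = pe + co + pp)
}

# majorant total coefficient (cm^-1) over the materials present, per photon
.ppt_majorant_mu <- function(mats, energy) {
  out <- rep(0, length(energy))
  for (m in mats) out <- pmax(out, mu_total(m, energy))
  out
}

# Vectorized delta-tracking of a photon batch to first real interaction or
# escape. pos mm (n x 3), dir unit (n x 3), energy MeV, time ns.
# Returns interactions (matrices) and, when keep_escaped, the escaping states.
.ppt_trace_batch <- function(grid, pos, dir, energy, time, history,
                             infinite_medium = FALSE, keep_escaped = FALSE) {
  mats <- lapply(grid$materials, ppt_material)
  n <- nrow(pos)
  out_idx <- integer(0); out_channel <- integer(0)
  esc_idx <- integer(0)
  act <- seq_len(n)
  center_mat <- .ppt_material_at(grid, matrix(0, 1, 3))
  guard <- 0L
  while (length(act)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("delta-tracking failed to terminate")
    e <- energy[act]
    mu_maj <- .ppt_majorant_mu(mats, e)            # cm^-1
    s <- stats::rexp(length(act)) / (mu_maj / 10)  # mm
    pos[act, ] <- pos[act, , drop = FALSE] + dir[act, , drop = FALSE] * s
    time[act] <- time[act] + s / .ppt_c_mm_ns
    matid <- if (infinite_medium) rep(center_mat, length(act))
             else .ppt_material_at(grid, pos[act, , drop = FALSE])
    outside <- matid == 0L
    if (any(outside)) {
      esc_idx <- c(esc_idx, act[outside])
    }
    inside <- which(!outside)
    if (length(inside)) {
      ai <- act[inside]
      mu <- .ppt_local_mu(mats, matid[inside], energy[ai])
      u <- stats::runif(length(ai)) * mu_maj[inside]
      real <- u < mu$total
      if (any(real)) {
        ri <- which(real)
        r <- stats::runif(length(ri)) * mu$total[ri]
        ch <- 1L + (r > mu$pe[ri]) + (r > mu$pe[ri] + mu$compton[ri])
        out_idx <- c(out_idx, ai[ri])
        out_channel <- c(out_channel, ch)
      }
      act <- ai[!real]
    } else {
      act <- integer(0)
    }
    act <- act  # null collisions stay active with unchanged state
  }
  list(
    idx = out_idx, channel = out_channel,
    pos = pos[out_idx, , drop = FALSE], dir = dir[out_idx, , drop = FALSE],
    energy = energy[out_idx], time = time[out_idx],
    history = history[out_idx],
    escaped = if (keep_escaped) list(
      idx = esc_idx, pos = pos[esc_idx, , drop = FALSE],
      dir = dir[esc_idx, , drop = FALSE], energy = energy[esc_idx],
      time = time[esc_idx], history = history[esc_idx]) else NULL,
    n_escaped = length(esc_idx)
  )
}

#' Trace a single photon to its first interaction or escape
#'
#' @param grid A `ppt_phantom`.
#' @param position Numeric length-3 start position in mm.
#' @param direction Numeric length-3 unit direction.
#' @param energy Photon energy in MeV.
#' @param time Start time in ns.
#' @param infinite_medium If `TRUE`, the material at the grid center fills
#'   all space and the photon cannot escape (free-path validation mode).
#' @return A one-row tibble with `channel` (`"escape"`, `"photoelectric"`,
#'   `"compton"`, `"pair"`), the interaction position `x`, `y`, `z` (mm),
#'   `energy` and `time`.
#' @export
trace_photon <- function(grid, position, direction, energy = 2.617, time = 0,
                         infinite_medium = FALSE) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("direction must be a unit vector", call. = FALSE)
  }
  tr <- .ppt_trace_batch(grid, matrix(position, 1), matrix(direction, 1),
                         energy, time, 1L, infinite_medium = infinite_medium,
                         keep_escaped = TRUE)
  if (length(tr$idx)) {
    tibble::tibble(
      channel = c("photoelectric", "compton", "pair")[tr$channel],
      x = tr$pos[1, 1], y = tr$pos[1, 2], z = tr$pos[1, 3],
      energy = tr$energy, time = tr$time)
  } else {
    tibble::tibble(channel = "escape", x = tr$escaped$pos[1, 1],
                   y = tr$escaped$pos[1, 2], z = tr$escaped$pos[1, 3],
                   energy = tr$escaped$energy, time = tr$escaped$time)
  }
}

#' Sample pair-production energy sharing
#'
#' Splits the available kinetic energy `e_gamma - 1.022` MeV between the
#' positron and electron. The default Bethe--Heitler-shaped sharing weights
#' the positron energy fraction x by `x^2 + (1-x)^2 + 2/3 x(1-x)`
#' (extreme-relativistic, no Coulomb correction); `"flat"` shares uniformly.
#' Both are symmetric under exchange of the two particles, so the sampling
#' distribution is centered at `(e_gamma - 1.022)/2`.
#'
#' @param e_gamma Photon energy in MeV, at least 1.022.
#' @param n Number of pairs to sample.
#' @param model `"bethe_heitler"` (default) or `"flat"`.
#' @return A tibble with columns `t_plus` and `t_minus` (MeV);
#'   `t_plus + t_minus == e_gamma - 1.022` exactly.
#' @export
sample_pair_energies <- function(e_gamma, n = 1,
                                 model = c("bethe_heitler", "flat")) {
  model <- match.arg(model)
  if (e_gamma < 1.022) {
    stop("pair production requires at least 1.022 MeV", call. = FALSE)
  }
  tt <- e_gamma - 1.022
  if (model == "flat") {
    x <- stats::runif(n)
  } else {
    x <- numeric(n); todo <- seq_len(n)
    while (length(todo)) {
      prop <- stats::runif(length(todo))
      w <- prop^2 + (1 - prop)^2 + 2 / 3 * prop * (1 - prop)
      ok <- stats::runif(length(todo)) < w
      x[todo[ok]] <- prop[ok]
      todo <- todo[!ok]
    }
  }
  tibble::tibble(t_plus = x * tt, t_minus = tt - x * tt)
}

#' Sample Compton scattering kinematics
#'
#' Draws the scattered-photon energy and polar angle from the
#' Klein--Nishina differential cross section by composition-rejection
#' sampling.
#'
#' @param e_gamma Incident photon energy in MeV (> 0).
#' @param n Number of samples.
#' @return A tibble with `energy` (scattered photon, MeV) and `angle`
#'   (polar scattering angle, rad).
#' @export
sample_compton <- function(e_gamma, n = 1) {
  stopifnot(e_gamma > 0)
  a <- e_gamma / 0.51099895
  eps0 <- 1 / (1 + 2 * a)
  a1 <- log(1 / eps0); a2 <- (1 - eps0^2) / 2
  eps <- numeric(n); ct <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    branch <- stats::runif(m) < a1 / (a1 + a2)
    r2 <- stats::runif(m)
    e <- ifelse(branch, exp(-a1 * r2), sqrt(eps0^2 + (1 - eps0^2) * r2))
    t <- (1 - e) / (a * e)
    sint2 <- t * (2 - t)
    g <- 1 - e * sint2 / (1 + e^2)
    ok <- stats::runif(m) < g
    eps[todo[ok]] <- e[ok]
    ct[todo[ok]] <- 1 - t[ok]
    todo <- todo[!ok]
  }
  tibble::tibble(energy = eps * e_gamma, angle = acos(pmin(1, pmax(-1, ct))))
}

# forward-peaked pair-particle polar angle: Gaussian with characteristic
# angle m_e c^2 / E_total
.ppt_pair_dirs <- function(photon_dir, ke) {
  theta_c <- 0.51099895 / (ke + 0.51099895)
  theta <- abs(stats::rnorm(length(ke), 0, theta_c))
  .ppt_rotate_dirs(photon_dir, theta)
}

#' Transport positrons to annihilation
#'
#' Condensed-history random walk: the CSDA path in the local material is
#' consumed in `steps` equal fractions, the direction is deflected each step
#' by a Gaussian multiple-scattering angle with standard deviation
#' `Es / (beta p c) * sqrt(step / X0)` (Es = 21.2 MeV), and the positron
#' annihilates at rest at the endpoint. Positrons that leave the grid escape
#' without annihilating (unless `infinite_medium`).
#'
#' @param ke Positron kinetic energies in MeV (vectorized).
#' @param r_p Production positions: an n x 3 matrix or data frame of mm
#'   coordinates (inside the grid).
#' @param grid A `ppt_phantom`.
#' @param dir0 Optional n x 3 matrix of initial directions (default
#'   isotropic).
#' @param time Production times in ns (default 0).
#' @param steps Number of condensed-history steps (default 20).
#' @param infinite_medium If `TRUE`, the central material fills all space.
#' @return A tibble with `x`, `y`, `z` (annihilation position, mm), `time`
#'   (ns), `range` (displacement `|r_a - r_p|`, mm) and `escaped`.
#' @export
transport_positron <- function(ke, r_p, grid, dir0 = NULL, time = 0,
                               steps = 20, infinite_medium = FALSE) {
  if (any(ke < 0)) stop("kinetic energy must be nonnegative", call. = FALSE)
  pos <- as.matrix(r_p)
  if (ncol(pos) != 3) stop("r_p must have three columns", call. = FALSE)
  n <- length(ke)
  if (nrow(pos) == 1 && n > 1) pos <- pos[rep(1, n), , drop = FALSE]
  if (!infinite_medium && any(.ppt_material_at(grid, pos) == 0L)) {
    stop("production position outside the grid", call. = FALSE)
  }
  mats <- lapply(grid$materials, ppt_material)
  center_mat <- .ppt_material_at(grid, matrix(0, 1, 3))
  if (is.null(dir0)) dir0 <- .ppt_iso_dirs(n)
  dir <- dir0
  start <- pos
  time <- rep_len(time, n)
  alive <- rep(TRUE, n)
  # total CSDA range in the production-site material fixes the path budget;
  # per-step geometric length rescales with the local material
  mat0 <- if (infinite_medium) rep(center_mat, n)
          else .ppt_material_at(grid, pos)
  range_total <- numeric(n)
  for (m in unique(mat0)) {
    sel <- mat0 == m
    range_total[sel] <- csda_range(mats[[m]], ke[sel])  # cm
  }
  for (i in seq_len(steps)) {
    idx <- which(alive & ke > 0)
    if (!length(idx)) break
    matid <- if (infinite_medium) rep(center_mat, length(idx))
             else .ppt_material_at(grid, pos[idx, , drop = FALSE])
    esc <- matid == 0L
    if (any(esc)) {
      alive[idx[esc]] <- FALSE
      idx <- idx[!esc]; matid <- matid[!esc]
    }
    if (!length(idx)) break
    frac_mid <- 1 - (i - 0.5) / steps
    step_cm <- numeric(length(idx))
    ke_mid <- numeric(length(idx))
    x0 <- numeric(length(idx))
    for (m in unique(matid)) {
      sel <- matid == m
      ii <- idx[sel]
      rm <- csda_range(mats[[m]], ke[ii])          # full range here
      step_cm[sel] <- rm / steps
      ke_mid[sel] <- .ppt_ke_from_range(mats[[m]], rm * frac_mid)
      x0[sel] <- mats[[m]]$x0_cm
    }
    ke_mid <- pmax(ke_mid, 1e-3)
    pc <- sqrt(ke_mid * (ke_mid + 2 * 0.51099895))
    beta <- pc / (ke_mid + 0.51099895)
    pos[idx, ] <- pos[idx, , drop = FALSE] + dir[idx, , drop = FALSE] * (step_cm * 5)
    theta <- abs(stats::rnorm(length(idx), 0,
                              21.2 / (beta * pc) * sqrt(step_cm / x0)))
    dir[idx, ] <- .ppt_rotate_dirs(dir[idx, , drop = FALSE], theta)
    pos[idx, ] <- pos[idx, , drop = FALSE] + dir[idx, , drop = FALSE] * (step_cm * 5)
    time[idx] <- time[idx] + step_cm * 10 / (pmax(beta, 0.05) * .ppt_c_mm_ns)
  }
  # positron must still be inside to annihilate
  if (!infinite_medium) {
    fin <- which(alive)
    out <- .ppt_material_at(grid, pos[fin, , drop = FALSE]) == 0L
    alive[fin[out]] <- FALSE
  }
  disp <- sqrt(rowSums((pos - start)^2))
  tibble::tibble(
    x = pos[, 1], y = pos[, 2], z = pos[, 3], time = time,
    range = disp, escaped = !alive
  )
}

#' Emit annihilation photon pairs
#'
#' Each annihilation produces two 511 keV photons along an isotropically
#' oriented axis, exactly back-to-back by default; optional acollinearity
#' perturbs the second photon by a Gaussian angle of the given FWHM.
#'
#' @param events A data frame of annihilation events with columns `x`, `y`,
#'   `z` (mm) and `time` (ns).
#' @param acollinearity_fwhm_deg Acollinearity FWHM in degrees (0 = exact
#'   back-to-back).
#' @return A tibble with two rows per event: `event` (row index in
#'   `events`), `photon` (1 or 2), origin `x`, `y`, `z`, direction `dx`,
#'   `dy`, `dz`, `energy` (0.511 MeV) and `time`.
#' @export
emit_annihilation_photons <- function(events, acollinearity_fwhm_deg = 0) {
  n <- nrow(events)
  axis <- .ppt_iso_dirs(n)
  d2 <- -axis
  if (acollinearity_fwhm_deg > 0) {
    sigma <- acollinearity_fwhm_deg * pi / 180 / (2 * sqrt(2 * log(2)))
    d2 <- .ppt_rotate_dirs(d2, abs(stats::rnorm(n, 0, sigma)))
  }
  tibble::tibble(
    event = rep(seq_len(n), 2),
    photon = rep(1:2, each = n),
    x = rep(events$x, 2), y = rep(events$y, 2), z = rep(events$z, 2),
    dx = c(axis[, 1], d2[, 1]), dy = c(axis[, 2], d2[, 2]),
    dz = c(axis[, 3], d2[, 3]),
    energy = 0.511, time = rep(events$time, 2)
  )
}

#' Simulation configuration
#'
#' @param track_secondaries Track Compton-scattered photons (which may
#'   themselves pair-produce). The first-interaction budget tally is always
#'   restricted to primaries.
#' @param track_annihilation_photons Track the 511 keV annihilation photons
#'   through the phantom and record the escaping states (needed for
#'   detection; can be disabled for profile/budget studies).
#' @param cutoff_mev Photon tracking cutoff in MeV.
#' @param positron_steps Condensed-history steps per positron.
#' @param pair_model `"bethe_heitler"` or `"flat"` energy sharing.
#' @param acollinearity_fwhm_deg Annihilation acollinearity FWHM (degrees).
#' @param infinite_medium Fill all space with the central material (no
#'   escape); used for free-path validation.
#' @param energy_mev Primary photon energy (default the 2.617 MeV line).
#' @param chunk_size Histories processed per vectorized chunk.
#' @return A list of class `ppt_config`.
#' @export
ppt_config <- function(track_secondaries = TRUE,
                       track_annihilation_photons = TRUE,
                       cutoff_mev = 0.05, positron_steps = 20,
                       pair_model = "bethe_heitler",
                       acollinearity_fwhm_deg = 0,
                       infinite_medium = FALSE, energy_mev = 2.617,
                       chunk_size = 1e6) {
  structure(list(
    track_secondaries = track_secondaries,
    track_annihilation_photons = track_annihilation_photons,
    cutoff_mev = cutoff_mev, positron_steps = positron_steps,
    pair_model = pair_model,
    acollinearity_fwhm_deg = acollinearity_fwhm_deg,
    infinite_medium = infinite_medium, energy_mev = energy_mev,
    chunk_size = chunk_size), class = "ppt_config")
}

#' Run a full simulation
#'
#' For each primary: sample the emission position and an isotropic
#' direction, track the photon to its first interaction (tallied per
#' history), follow Compton-scattered secondaries when enabled, convert pair
#' productions into positron transports and annihilations, and optionally
#' track the annihilation photons out of the phantom.
#'
#' @param grid A `ppt_phantom`.
#' @param n_primaries Number of primary photons (>= 0).
#' @param config A [ppt_config()].
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return A `ppt_eventlog`: a list with `n_primaries`, `first_channel`
#'   (integer per history: 0 none, 1 photoelectric, 2 Compton, 3 pair),
#'   `pairs`, `annihilations` and `photons` tibbles, and the config.
#' @export
run_simulation <- function(grid, n_primaries, config = ppt_config(),
                           seed = 1) {
  stopifnot(inherits(grid, "ppt_phantom"), n_primaries >= 0)
  set.seed(seed)
  cfg <- config
  first_channel <- integer(n_primaries)
  pairs_acc <- list(); ann_acc <- list(); phot_acc <- list()
  done <- 0L
  while (done < n_primaries) {
    n <- as.integer(min(cfg$chunk_size, n_primaries - done))
    hist_ids <- done + seq_len(n)
    em <- sample_emission(grid, n)
    pos <- cbind(em$x, em$y, em$z)
    dir <- .ppt_iso_dirs(n)
    energy <- rep(cfg$energy_mev, n)
    time <- rep(0, n)
    pair_pos <- NULL; pair_dir <- NULL; pair_e <- NULL
    pair_t <- NULL; pair_h <- NULL; pair_primary <- NULL
    gen <- 0L
    repeat {
      tr <- .ppt_trace_batch(grid, pos, dir, energy, time, hist_ids,
                             infinite_medium = cfg$infinite_medium)
      if (gen == 0L) {
        first_channel[tr$history] <- tr$channel
      }
      is_pair <- tr$channel == 3L
      if (any(is_pair)) {
        pair_pos <- rbind(pair_pos, tr$pos[is_pair, , drop = FALSE])
        pair_dir <- rbind(pair_dir, tr$dir[is_pair, , drop = FALSE])
        pair_e <- c(pair_e, tr$energy[is_pair])
        pair_t <- c(pair_t, tr$time[is_pair])
        pair_h <- c(pair_h, tr$history[is_pair])
        pair_primary <- c(pair_primary, rep(gen == 0L, sum(is_pair)))
      }
      is_c <- tr$channel == 2L
      if (!cfg$track_secondaries || !any(is_c)) break
      sc <- sample_compton_each(tr$energy[is_c])
      keep <- sc$energy >= cfg$cutoff_mev
      if (!any(keep)) break
      pos <- tr$pos[is_c, , drop = FALSE][keep, , drop = FALSE]
      dir <- .ppt_rotate_dirs(tr$dir[is_c, , drop = FALSE][keep, , drop = FALSE],
                              sc$angle[keep])
      energy <- sc$energy[keep]
      time <- tr$time[is_c][keep]
      hist_ids <- tr$history[is_c][keep]
      gen <- gen + 1L
      if (gen > 50L) break
    }
    if (length(pair_h)) {
      pe <- sample_pair_energies_vec(pair_e, cfg$pair_model)
      dplus <- .ppt_pair_dirs(pair_dir, pe$t_plus)
      ann <- transport_positron(pe$t_plus, pair_pos, grid, dir0 = dplus,
                                time = pair_t, steps = cfg$positron_steps,
                                infinite_medium = cfg$infinite_medium)
      pairs_acc[[length(pairs_acc) + 1L]] <- tibble::tibble(
        history = pair_h, x = pair_pos[, 1], y = pair_pos[, 2],
        z = pair_pos[, 3], t_plus = pe$t_plus, t_minus = pe$t_minus,
        time = pair_t, from_primary = pair_primary)
      ok <- !ann$escaped
      ann_tb <- tibble::tibble(
        history = pair_h[ok], x = ann$x[ok], y = ann$y[ok], z = ann$z[ok],
        time = ann$time[ok],
        range = ann$range[ok])
      ann_acc[[length(ann_acc) + 1L]] <- ann_tb
      if (cfg$track_annihilation_photons && nrow(ann_tb)) {
        ph <- emit_annihilation_photons(ann_tb, cfg$acollinearity_fwhm_deg)
        phot_acc[[length(phot_acc) + 1L]] <-
          .ppt_track_annihilation_photons(grid, ph, ann_tb$history, cfg)
      }
    }
    done <- done + n
  }
  structure(list(
    n_primaries = n_primaries,
    first_channel = first_channel,
    pairs = if (length(pairs_acc)) dplyr::bind_rows(pairs_acc) else
      tibble::tibble(history = integer(), x = numeric(), y = numeric(),
                     z = numeric(), t_plus = numeric(), t_minus = numeric(),
                     time = numeric(), from_primary = logical()),
    annihilations = if (length(ann_acc)) dplyr::bind_rows(ann_acc) else
      tibble::tibble(history = integer(), x = numeric(), y = numeric(),
                     z = numeric(), time = numeric(), range = numeric()),
    photons = if (length(phot_acc)) dplyr::bind_rows(phot_acc) else
      tibble::tibble(history = integer(), x = numeric(), y = numeric(),
                     z = numeric(), dx = numeric(), dy = numeric(),
                     dz = numeric(), energy = numeric(), time = numeric(),
                     scattered = logical()),
    config = cfg, seed = seed,
    grid_shape = grid$shape, voxel_mm = grid$voxel_mm
  ), class = "ppt_eventlog")
}

# Compton sampling at per-photon energies (vectorized rejection)
sample_compton_each <- function(e_gamma) {
  n <- length(e_gamma)
  a <- e_gamma / 0.51099895
  eps0 <- 1 / (1 + 2 * a)
  a1 <- log(1 / eps0); a2 <- (1 - eps0^2) / 2
  eps <- numeric(n); ct <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    branch <- stats::runif(m) < (a1[todo] / (a1[todo] + a2[todo]))
    r2 <- stats::runif(m)
    e <- ifelse(branch, exp(-a1[todo] * r2),
                sqrt(eps0[todo]^2 + (1 - eps0[todo]^2) * r2))
    t <- (1 - e) / (a[todo] * e)
    g <- 1 - e * t * (2 - t) / (1 + e^2)
    ok <- stats::runif(m) < g
    eps[todo[ok]] <- e[ok]
    ct[todo[ok]] <- 1 - t[ok]
    todo <- todo[!ok]
  }
  list(energy = eps * e_gamma, angle = acos(pmin(1, pmax(-1, ct))))
}

# pair energy sharing at per-photon energies
sample_pair_energies_vec <- function(e_gamma, model) {
  tt <- e_gamma - 1.022
  n <- length(tt)
  if (model == "flat") {
    x <- stats::runif(n)
  } else {
    x <- numeric(n); todo <- seq_len(n)
    while (length(todo)) {
      prop <- stats::runif(length(todo))
      w <- prop^2 + (1 - prop)^2 + 2 / 3 * prop * (1 - prop)
      ok <- stats::runif(length(todo)) < w
      x[todo[ok]] <- prop[ok]
      todo <- todo[!ok]
    }
  }
  list(t_plus = x * tt, t_minus = tt - x * tt)
}

# track annihilation photons through the phantom; Compton scatters update
# origin/direction/energy, photoelectric absorbs, escapes are recorded
.ppt_track_annihilation_photons <- function(grid, ph, ann_history, cfg) {
  pos <- cbind(ph$x, ph$y, ph$z)
  dir <- cbind(ph$dx, ph$dy, ph$dz)
  energy <- ph$energy
  time <- ph$time
  ids <- seq_len(nrow(ph))
  history <- ann_history[ph$event]
  event <- ph$event
  scattered <- rep(FALSE, nrow(ph))
  out <- list()
  guard <- 0L
  while (length(ids)) {
    guard <- guard + 1L
    if (guard > 60L) break
    tr <- .ppt_trace_batch(grid, pos, dir, energy, time, ids,
                           keep_escaped = TRUE)
    esc <- tr$escaped
    if (length(esc$idx)) {
      sel <- match(esc$idx, ids)
      # origin and start time of the escaping leg; the detector adds the
      # geometric flight time from here to the ring
      out[[length(out) + 1L]] <- tibble::tibble(
        history = history[sel], event = event[sel],
        x = pos[sel, 1], y = pos[sel, 2], z = pos[sel, 3],
        dx = dir[sel, 1], dy = dir[sel, 2], dz = dir[sel, 3],
        energy = energy[sel], time = time[sel],
        scattered = scattered[sel])
    }
    is_c <- tr$channel == 2L
    if (!any(is_c)) break
    sel <- match(tr$idx[is_c], ids)
    sc <- sample_compton_each(tr$energy[is_c])
    keep <- sc$energy >= cfg$cutoff_mev
    sel <- sel[keep]
    if (!length(sel)) break
    pos <- tr$pos[is_c, , drop = FALSE][keep, , drop = FALSE]
    dir <- .ppt_rotate_dirs(tr$dir[is_c, , drop = FALSE][keep, , drop = FALSE],
                            sc$angle[keep])
    energy <- sc$energy[keep]
    time <- tr$time[is_c][keep]
    history <- history[sel]
    event <- event[sel]
    scattered <- rep(TRUE, length(sel))
    ids <- seq_along(sel)
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(history = integer(), event = integer(), x = numeric(),
                   y = numeric(), z = numeric(), dx = numeric(),
                   dy = numeric(), dz = numeric(), energy = numeric(),
                   time = numeric(), scattered = logical())
}

#' @export
print.ppt_eventlog <- function(x, ...) {
  tab <- interaction_fractions(x)
  cat(sprintf("<ppt_eventlog> %s primaries (seed %s)\n",
              format(x$n_primaries, big.mark = ","), x$seed))
  cat(sprintf("  first interaction: %s\n",
              paste(sprintf("%s %.3g%%", tab$channel, 100 * tab$fraction),
                    collapse = ", ")))
  cat(sprintf("  pair events: %d   annihilations: %d   escaping photons: %d\n",
              nrow(x$pairs), nrow(x$annihilations), nrow(x$photons)))
  invisible(x)
}
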