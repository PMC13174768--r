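# shared simulation fixtures, built once per session on first use
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

water_cube_log <- function() memo("water_cube_log", {
  run_simulation(build_cube(100, "water", "point"), 1e6,
                 ppt_config(track_annihilation_photons = FALSE), seed = 101)
})

# annihilations/pairs from the shared run as plain event tables
water_pairs <- function() water_cube_log()$pairs

# Rayleigh-style uniformity statistic for directions on the sphere:
# 3 n |mean vector|^2 ~ chi-squared(3) under uniformity
rayleigh_stat <- function(dirs) {
  m <- colMeans(dirs)
  3 * nrow(dirs) * sum(m^2)
}

# rotate positions/directions about the z axis
rotate_z <- function(df, angle) {
  cs <- cos(angle); sn <- sin(angle)
  out <- df
  out$x <- cs * df$x - sn * df$y
  out$y <- sn * df$x + cs * df$y
  out$dx <- cs * df$dx - sn * df$dy
  out$dy <- sn * df$dx + cs * df$dy
  out
}

# synthetic clean coincidences: LORs through given source points
synthetic_coincidences <- function(points, n_per, ring) {
  all <- list()
  for (p in seq_len(nrow(points))) {
    u <- stats::runif(n_per, -0.3, 0.3)
    ph <- stats::runif(n_per, 0, 2 * pi)
    st <- sqrt(1 - u^2)
    d <- cbind(st * cos(ph), st * sin(ph), u)
    px <- points[p, 1]; py <- points[p, 2]; pz <- points[p, 3]
    a <- d[, 1]^2 + d[, 2]^2
    b <- px * d[, 1] + py * d[, 2]
    disc <- sqrt(pmax(0, b^2 - a * (px^2 + py^2 - ring$radius_mm^2)))
    tp <- (-b + disc) / a
    tm <- (b + disc) / a
    all[[p]] <- tibble::tibble(
      history = seq_len(n_per) + (p - 1L) * n_per,
      iphi1 = 1L, iz1 = 1L, iphi2 = 1L, iz2 = 1L,
      x1 = px + d[, 1] * tp, y1 = py + d[, 2] * tp, z1 = pz + d[, 3] * tp,
      x2 = px - d[, 1] * tm, y2 = py - d[, 2] * tm, z2 = pz - d[, 3] * tm,
      e1_kev = 511, e2_kev = 511,
      dt_ns = (tp - tm) / 299.792458)
  }
  out <- dplyr::bind_rows(all)
  attr(out, "ring") <- ring
  class(out) <- c("ppt_coincidences", class(out))
  out
}
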