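test_that("slice_profile bins events and enforces the slab", {
  ev <- tibble::tibble(x = rep(0, 100), y = 0, z = 0)
  pr <- slice_profile(ev, "x")
  expect_equal(sum(pr$counts > 0), 1)
  expect_equal(pr$counts[pr$counts > 0], 100)
  expect_true(all(diff(pr$x) > 0))

  far <- tibble::tibble(x = stats::rnorm(50), y = 50, z = 50)
  expect_error(slice_profile(far, "x"), "projection")
  expect_error(slice_profile(far[0, ], "x"), "no events")
})

test_that("projection profiles are at least as wide as slice profiles", {
  log <- water_cube_log()
  width <- function(mode) {
    pr <- slice_profile(log$pairs, "x", mode = mode, bin_mm = 1)
    fit_profile(pr)$fwhm
  }
  expect_gte(width("projection"), width("slice"))
})

test_that("production profiles from the cube run are symmetric", {
  # the slab profile has heavy 1/x^2 tails, so test symmetry robustly:
  # the median sits at the origin and left/right counts balance
  log <- water_cube_log()
  v <- log$pairs$x[abs(log$pairs$y) <= 5 & abs(log$pairs$z) <= 5]
  expect_lt(abs(stats::median(v)), 0.25)
  p_right <- mean(v > 0)
  expect_lt(abs(p_right - 0.5), 3 * sqrt(0.25 / length(v)))
})

test_that("fit_profile recovers a pure Lorentzian exactly", {
  x <- seq(-20, 20, by = 0.25)
  y <- 1 / (1 + (x / 0.45)^2)
  pr <- structure(tibble::tibble(x = x, counts = y * 1e4, value = y),
                  bin_mm = 0.25, mode = "slice", coord = "x",
                  half_thickness_mm = 1, n_events = 1e4, normalized = TRUE,
                  class = c("ppt_profile", class(tibble::tibble())))
  fit <- fit_profile(pr)
  expect_equal(fit$fwhm, 0.9, tolerance = 0.01)
  expect_lt(fit$B, 0.01)
  expect_equal(glance(fit)$fwhm, fit$fwhm)
  expect_equal(nrow(tidy(fit)), 4)
})

test_that("fit_profile recovers exponential-background parameters from samples", {
  set.seed(41)
  cc <- 0.35
  v <- stats::rexp(1e5, cc) * sample(c(-1, 1), 1e5, replace = TRUE)
  pr <- slice_profile(tibble::tibble(x = v, y = 0, z = 0), "x",
                      bin_mm = 0.5, range_mm = 25, normalize = FALSE)
  fit <- fit_profile(pr, fixed = list(A = 0))
  expect_equal(fit$C, cc, tolerance = 0.05)
  # two-sided exponential density: expected peak height n * bin * C / 2
  expect_equal(fit$B, 1e5 * 0.5 * cc / 2, tolerance = 0.05)
  expect_identical(fit$A, 0)
})

test_that("fit_profile recovers all four parameters from exact-model data", {
  set.seed(43)
  truth <- c(A = 0.8, sigma = 1.2, B = 0.25, C = 0.2)
  x <- seq(-30, 30, by = 0.25)
  f <- truth[["A"]] / (1 + (x / truth[["sigma"]])^2) +
    truth[["B"]] * exp(-truth[["C"]] * abs(x))
  # multinomial counts at n = 1e5 emulate histogram noise
  n <- 1e5
  cnt <- stats::rmultinom(1, n, f / sum(f))[, 1]
  pr <- structure(tibble::tibble(x = x, counts = cnt,
                                 value = cnt / max(cnt)),
                  bin_mm = 0.25, mode = "slice", coord = "x",
                  half_thickness_mm = 1, n_events = n, normalized = TRUE,
                  class = c("ppt_profile", class(tibble::tibble())))
  fit <- fit_profile(pr)
  # the peak normalization scales A and B jointly, so compare shape
  # parameters and the A/B ratio
  rel <- c(fit$sigma / truth[["sigma"]], fit$C / truth[["C"]],
           (fit$A / fit$B) / (truth[["A"]] / truth[["B"]]))
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("degenerate profiles are rejected", {
  flat <- structure(tibble::tibble(x = seq(-5, 5, 0.5),
                                   counts = rep(3, 21),
                                   value = rep(1, 21)),
                    bin_mm = 0.5, mode = "slice", coord = "x",
                    half_thickness_mm = 1, n_events = 63, normalized = TRUE,
                    class = c("ppt_profile", class(tibble::tibble())))
  expect_error(fit_profile(flat), "flat|converge")
  small <- flat[1:5, ]
  expect_error(fit_profile(small), "10 occupied")
})

test_that("positron statistics summarize the event log", {
  log <- water_cube_log()
  ps <- positron_stats(log)
  expect_equal(ps$ke_center, (2.617 - 1.022) / 2, tolerance = 0.02)
  expect_equal(ps$percentiles$percentile, c(50, 90, 99, 99.9))
  expect_true(all(diff(ps$percentiles$range_mm) > 0))
  tiny <- log; tiny$pairs <- log$pairs[1:10, ]
  expect_error(positron_stats(tiny), "100 pair")
})

test_that("interaction fractions partition histories and match the oracle", {
  log <- water_cube_log()
  fr <- interaction_fractions(log)
  expect_equal(sum(fr$fraction), 1)
  for (side in c(1, 5, 10)) {
    g <- build_cube(side * 10, "water", "point")
    mc <- interaction_fractions(
      run_simulation(g, 2e5, ppt_config(track_secondaries = FALSE,
                                        track_annihilation_photons = FALSE),
                     seed = 50 + side))
    or <- interaction_fractions_oracle("water", 2.617, side)
    for (ch in c("none", "compton", "pair")) {
      p <- or$fraction[or$channel == ch]
      se <- sqrt(p * (1 - p) / 2e5)
      expect_lt(abs(mc$fraction[mc$channel == ch] - p), 3 * se + 1e-12)
    }
  }
})

test_that("infinite-medium and vacuum limits of the budget", {
  g <- build_cube(10, "water", "point")
  inf <- run_simulation(g, 5e3, ppt_config(track_secondaries = FALSE,
                                           track_annihilation_photons = FALSE,
                                           infinite_medium = TRUE), seed = 61)
  expect_equal(interaction_fractions(inf)$fraction[1], 0)
  vac <- run_simulation(build_cube(10, "air", "point"), 5e3,
                        ppt_config(track_secondaries = FALSE,
                                   track_annihilation_photons = FALSE),
                        seed = 62)
  expect_gt(interaction_fractions(vac)$fraction[1], 0.999)
})

test_that("pair efficiency counts the central ROI per primary", {
  log <- water_cube_log()
  eff <- pair_efficiency(log, 10)
  expect_gt(eff$production_efficiency, 0)
  expect_lte(eff$annihilation_efficiency, 1)
  expect_error(pair_efficiency(log, 500), "larger than the phantom")
  # infinite medium: no positron escape, production count = annihilation count
  g <- build_cube(20, "water", "point")
  inf <- run_simulation(g, 5e4, ppt_config(track_secondaries = FALSE,
                                           track_annihilation_photons = FALSE,
                                           infinite_medium = TRUE), seed = 63)
  expect_equal(nrow(inf$pairs), nrow(inf$annihilations))
})
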