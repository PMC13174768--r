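test_that("free paths in infinite water reproduce the mean free path", {
  g <- build_cube(50, "water", "point")
  set.seed(5)
  n <- 1e5
  pos <- matrix(0, n, 3)
  dir <- pptsim:::.ppt_iso_dirs(n)
  tr <- pptsim:::.ppt_trace_batch(g, pos, dir, rep(2.617, n), rep(0, n),
                                  seq_len(n), infinite_medium = TRUE)
  d_cm <- sqrt(rowSums(tr$pos^2)) / 10
  expect_equal(mean(d_cm), 23.4, tolerance = 0.01)
  # delta-tracking free paths agree with direct exponential sampling
  ks <- stats::ks.test(d_cm[seq_len(1e4)], "pexp",
                       rate = mu_total("water", 2.617))
  expect_gt(ks$p.value, 0.01)
})

test_that("vacuum-like grids let photons escape", {
  g <- build_cube(10, "air", "point")
  set.seed(2)
  log <- run_simulation(g, 500, ppt_config(track_secondaries = FALSE,
                                           track_annihilation_photons = FALSE),
                        seed = 2)
  expect_true(all(log$first_channel == 0L))
})

test_that("two-material slab transmission matches the closed form", {
  # 40 mm water | 40 mm bone slab along +x, photons enter at x = -40
  g <- build_cube(80, "water", "point", voxel_mm = 2)
  g$materials <- c("water", "bone")
  g$material_map[21:40, , ] <- 2L
  n <- 2e4
  set.seed(9)
  pos <- cbind(rep(-39.9, n), 0, 0)
  dir <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  tr <- pptsim:::.ppt_trace_batch(g, pos, dir, rep(2.617, n), rep(0, n),
                                  seq_len(n))
  p_trans <- 1 - length(tr$idx) / n
  p_exp <- exp(-mu_total("water", 2.617) * 3.99 - mu_total("bone", 2.617) * 4)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_trans - p_exp), 3 * se)
})

test_that("trace_photon validates direction and reports escape", {
  g <- build_cube(10, "water", "point")
  expect_error(trace_photon(g, c(0, 0, 0), c(1, 1, 0)), "unit vector")
  set.seed(1)
  out <- trace_photon(g, c(0, 0, 0), c(1, 0, 0), energy = 2.617)
  expect_true(out$channel %in% c("escape", "compton", "pair", "photoelectric"))
})

test_that("pair energy sharing conserves energy and is symmetric", {
  expect_error(sample_pair_energies(0.9, 1), "1.022")
  set.seed(3)
  thr <- sample_pair_energies(1.022, 10)
  expect_true(all(thr$t_plus == 0 & thr$t_minus == 0))
  pe <- sample_pair_energies(2.617, 2e4)
  expect_true(all(abs(pe$t_plus + pe$t_minus - 1.595) < 1e-12))
  expect_true(all(pe$t_plus >= 0 & pe$t_minus >= 0))
  # exchange symmetry: the two marginals agree
  expect_lt(abs(mean(pe$t_plus) - mean(pe$t_minus)), 0.015)
  expect_lt(abs(stats::median(pe$t_plus) - stats::median(pe$t_minus)), 0.03)
  flat <- sample_pair_energies(2.617, 2e4, model = "flat")
  expect_equal(mean(flat$t_plus), 1.595 / 2, tolerance = 0.02)
})

test_that("Compton sampling follows Klein-Nishina", {
  set.seed(4)
  e0 <- 2.617
  sc <- sample_compton(e0, 2e4)
  emin <- e0 / (1 + 2 * e0 / 0.51099895)
  expect_true(all(sc$energy <= e0 + 1e-12))
  expect_true(all(sc$energy >= emin - 1e-9))
  # quadrature oracle for the mean scattered energy
  a <- e0 / 0.51099895
  # dsigma/deps ~ (eps + 1/eps - sin^2 theta); integrate numerically
  f <- function(eps) {
    ct <- 1 - (1 - eps) / (a * eps)
    eps + 1 / eps - (1 - ct^2)
  }
  lo <- 1 / (1 + 2 * a)
  norm <- stats::integrate(f, lo, 1)$value
  mean_eps <- stats::integrate(function(e) e * f(e), lo, 1)$value / norm
  expect_equal(mean(sc$energy), mean_eps * e0, tolerance = 0.02)
})

test_that("positron transport keeps displacement within the CSDA bound", {
  g <- build_cube(100, "water", "point")
  set.seed(6)
  still <- transport_positron(rep(0, 10), matrix(0, 10, 3), g)
  expect_true(all(still$range == 0))
  ke <- stats::runif(2000, 0.05, 1.5)
  tp <- transport_positron(ke, matrix(0, 2000, 3), g,
                           infinite_medium = TRUE)
  bound <- csda_range("water", ke) * 10 + sqrt(3)
  expect_true(all(tp$range <= bound))
  expect_error(transport_positron(0.5, matrix(200, 1, 3), g), "outside")
})

test_that("annihilation photons are back-to-back with isotropic axes", {
  set.seed(8)
  ev <- tibble::tibble(x = stats::rnorm(1e4), y = stats::rnorm(1e4),
                       z = stats::rnorm(1e4), time = 0)
  ph <- emit_annihilation_photons(ev)
  d1 <- as.matrix(ph[ph$photon == 1, c("dx", "dy", "dz")])
  d2 <- as.matrix(ph[ph$photon == 2, c("dx", "dy", "dz")])
  expect_lt(max(abs(d1 + d2)), 1e-9)
  expect_equal(unique(ph$energy), 0.511)
  # Rayleigh-type uniformity: 3n|mean|^2 ~ chi2(3)
  expect_lt(rayleigh_stat(d1), stats::qchisq(0.99, 3))

  ph2 <- emit_annihilation_photons(ev, acollinearity_fwhm_deg = 0.5)
  d1 <- as.matrix(ph2[ph2$photon == 1, c("dx", "dy", "dz")])
  d2 <- as.matrix(ph2[ph2$photon == 2, c("dx", "dy", "dz")])
  ang <- acos(pmin(1, rowSums(d1 * (-d2)))) * 180 / pi
  fwhm <- 2 * sqrt(2 * log(2)) * sqrt(mean(ang^2))
  expect_equal(fwhm, 0.5, tolerance = 0.1)
})

test_that("run_simulation is seeded, conserves energy and tallies channels", {
  g <- build_cube(10, "water", "point")
  empty <- run_simulation(g, 0, seed = 1)
  expect_equal(nrow(empty$pairs), 0)

  cfg <- ppt_config(track_secondaries = FALSE,
                    track_annihilation_photons = FALSE)
  a <- run_simulation(g, 2e4, cfg, seed = 33)
  b <- run_simulation(g, 2e4, cfg, seed = 33)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$first_channel, b$first_channel)

  big <- run_simulation(g, 3e5, cfg, seed = 12)
  expect_true(all(abs(big$pairs$t_plus + big$pairs$t_minus + 1.022 - 2.617)
                  < 1e-9))
  mc <- interaction_fractions(big)
  or <- interaction_fractions_oracle("water", 2.617, 1)
  for (ch in c("none", "compton", "pair")) {
    p <- or$fraction[or$channel == ch]
    se <- sqrt(p * (1 - p) / 3e5)
    expect_lt(abs(mc$fraction[mc$channel == ch] - p), 3 * se + 1e-12)
  }
  # every annihilation has a parent pair event; only escapes reduce them
  expect_lte(nrow(big$annihilations), nrow(big$pairs))
})

test_that("positron range broadens annihilation profiles beyond production", {
  log <- water_cube_log()
  sp <- function(d) {
    v <- d$x[abs(d$y) <= 3 & abs(d$z) <= 3]
    stats::IQR(v)
  }
  expect_gte(sp(log$annihilations), sp(log$pairs))
})
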