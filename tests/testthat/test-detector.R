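ideal_ring <- function(...) {
  detector_ring("preclinical", energy_res_fwhm = 0, timing_fwhm_ps = 0,
                tau_ns = 10, ...)
}

test_that("a central back-to-back pair hits antipodal crystals", {
  ring <- ideal_ring()
  ph <- tibble::tibble(
    history = c(1L, 1L), x = 0, y = 0, z = 0,
    dx = c(1, -1), dy = 0, dz = 0, energy = 0.511, time = 0)
  set.seed(1)
  hits <- detect_singles(ph, ring)
  expect_equal(nrow(hits), 2)
  dphi <- abs(hits$iphi[1] - hits$iphi[2])
  expect_lt(abs(dphi - ring$n_phi / 2), 1.5)
  coin <- sort_coincidences(hits, ring)
  expect_equal(nrow(coin), 1)
  expect_lte(abs(coin$dt_ns), ring$tau_ns)
})

test_that("photons along the ring axis escape axially", {
  ring <- ideal_ring()
  ph <- tibble::tibble(history = 1L, x = 0, y = 0, z = 0,
                       dx = 0, dy = 0, dz = 1, energy = 0.511, time = 0)
  expect_equal(nrow(detect_singles(ph, ring)), 0)
})

test_that("energy blur reproduces the configured resolution", {
  ring <- detector_ring("preclinical", energy_res_fwhm = 0.1,
                        timing_fwhm_ps = 0)
  n <- 1e4
  set.seed(11)
  u <- stats::runif(n, -0.3, 0.3); phv <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - u^2)
  ph <- tibble::tibble(history = seq_len(n), x = 0, y = 0, z = 0,
                       dx = st * cos(phv), dy = st * sin(phv), dz = u,
                       energy = 0.511, time = 0)
  hits <- detect_singles(ph, ring)
  fwhm <- 2 * sqrt(2 * log(2)) * stats::sd(hits$energy_kev)
  expect_equal(fwhm, 51.1, tolerance = 0.05)
})

test_that("energy window and multiplicity rules reject events", {
  ring <- ideal_ring()
  base <- tibble::tibble(history = 1L, iphi = c(1L, 200L), iz = 40L,
                         hx = 0, hy = 0, hz = 0,
                         energy_kev = c(511, 239), time = 0)
  expect_equal(nrow(sort_coincidences(base, ring)), 0)  # 239 keV line excluded
  three <- tibble::tibble(history = 1L, iphi = c(1L, 150L, 300L), iz = 40L,
                          hx = 0, hy = 0, hz = 0,
                          energy_kev = 511, time = c(0, 1e-3, 2e-3))
  expect_equal(nrow(sort_coincidences(three, ring)), 0)  # multiple rejection
  late <- tibble::tibble(history = 1L, iphi = c(1L, 200L), iz = 40L,
                         hx = 0, hy = 0, hz = 0,
                         energy_kev = 511, time = c(0, 50))
  expect_equal(nrow(sort_coincidences(late, ring)), 0)   # outside tau
})

test_that("with an ideal ring every geometrically accepted pair coincides", {
  ring <- ideal_ring()
  set.seed(13)
  n <- 4000
  ev <- tibble::tibble(x = stats::runif(n, -10, 10),
                       y = stats::runif(n, -10, 10),
                       z = stats::runif(n, -10, 10), time = 0)
  ph <- emit_annihilation_photons(ev)
  ph$history <- ph$event
  hits <- detect_singles(ph, ring)
  coin <- sort_coincidences(hits, ring)
  # independent geometric count: both photons inside the axial extent
  half <- ring$axial_mm / 2
  hit_z <- function(p) {
    a <- p$dx^2 + p$dy^2
    b <- 2 * (p$x * p$dx + p$y * p$dy)
    cc <- p$x^2 + p$y^2 - ring$radius_mm^2
    t <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    p$z + p$dz * t
  }
  z1 <- hit_z(ph[ph$photon == 1, ])
  z2 <- hit_z(ph[ph$photon == 2, ])
  expect_equal(nrow(coin), sum(abs(z1) <= half & abs(z2) <= half))
})

test_that("coincidence count is monotone in the energy window", {
  ring_wide <- detector_ring("preclinical", energy_res_fwhm = 0.15,
                             energy_window_kev = c(350, 650))
  set.seed(14)
  n <- 3000
  ev <- tibble::tibble(x = 0, y = 0, z = stats::runif(n, -5, 5), time = 0)
  ph <- emit_annihilation_photons(ev)
  ph$history <- ph$event
  hits <- detect_singles(ph, ring_wide)
  counts <- sapply(list(c(350, 650), c(435, 585), c(490, 530)), function(w) {
    r <- ring_wide; r$energy_window_kev <- w
    nrow(sort_coincidences(hits, r))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("rotating phantom and ring together preserves coincidence counts", {
  g <- build_cube(30, "water", "point")
  log <- run_simulation(g, 5e5,
                        ppt_config(track_annihilation_photons = TRUE),
                        seed = 17)
  ring <- detector_ring("preclinical")
  set.seed(5); n0 <- nrow(sort_coincidences(detect_singles(log$photons, ring),
                                            ring))
  set.seed(5)
  rot <- rotate_z(log$photons, 37 * pi / 180)
  n1 <- nrow(sort_coincidences(detect_singles(rot, ring), ring))
  expect_lt(abs(n0 - n1), 3 * sqrt(max(n0, 1)))
})

test_that("list-mode files round-trip", {
  ring <- ideal_ring()
  set.seed(19)
  ev <- tibble::tibble(x = 0, y = 0, z = stats::runif(50, -5, 5), time = 0)
  ph <- emit_annihilation_photons(ev)
  ph$history <- ph$event
  coin <- sort_coincidences(detect_singles(ph, ring), ring)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_listmode(coin, ring, path)
  back <- read_listmode(path)
  expect_equal(nrow(back), nrow(coin))
  expect_equal(back$x1, coin$x1, tolerance = 1e-6)
})
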