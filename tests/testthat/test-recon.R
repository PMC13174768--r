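test_that("lor_path traverses voxels exactly", {
  g <- image_geometry(c(10, 10, 10), 1)
  # axis-aligned LOR through a row of 1 mm voxels
  p <- lor_path(g, c(-20, -4.5, -4.5), c(20, -4.5, -4.5))
  expect_equal(nrow(p), 10)
  expect_equal(p$length_mm, rep(1, 10))
  # diagonal of a single 1 mm voxel
  g1 <- image_geometry(c(1, 1, 1), 1)
  pd <- lor_path(g1, c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5))
  expect_equal(nrow(pd), 1)
  expect_equal(pd$length_mm, sqrt(3), tolerance = 1e-9)
  # degenerate LOR
  expect_equal(nrow(lor_path(g, c(1, 1, 1), c(1, 1, 1))), 0)
})

test_that("lor_path lengths sum to the chord length (dense-sampling oracle)", {
  g <- image_geometry(c(32, 32, 32), 1.5)
  set.seed(21)
  for (i in 1:25) {
    p1 <- stats::rnorm(3, sd = 60); p1 <- p1 / sqrt(sum(p1^2)) * 80
    p2 <- -p1 + stats::rnorm(3, sd = 10)
    path <- lor_path(g, p1, p2)
    tt <- seq(1e-6, 1 - 1e-6, length.out = 40001)
    pts <- cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]),
                 p1[3] + tt * (p2[3] - p1[3]))
    inside <- abs(pts[, 1]) <= 24 & abs(pts[, 2]) <= 24 & abs(pts[, 3]) <= 24
    chord <- mean(inside) * sqrt(sum((p2 - p1)^2))
    expect_equal(sum(path$length_mm), chord, tolerance = 5e-3)
  }
})

test_that("MLEM localizes a central point source within one voxel", {
  ring <- detector_ring("preclinical", energy_res_fwhm = 0,
                        timing_fwhm_ps = 0)
  set.seed(23)
  coin <- synthetic_coincidences(matrix(c(0, 0, 0), 1), 1500, ring)
  geom <- image_geometry(c(41, 41, 41), 1)
  img <- mlem_reconstruct(coin, geom, n_iter = 20)
  expect_true(all(img >= 0))
  mx <- which(img == max(img), arr.ind = TRUE)
  expect_true(all(abs(mx - 21) <= 1))
})

test_that("one EM iteration on a single LOR supports only that LOR", {
  ring <- detector_ring("preclinical", energy_res_fwhm = 0,
                        timing_fwhm_ps = 0)
  coin <- tibble::tibble(history = 1L, iphi1 = 1L, iz1 = 1L, iphi2 = 1L,
                         iz2 = 1L, x1 = -80, y1 = 0.2, z1 = 0.3, x2 = 80,
                         y2 = 0.2, z2 = 0.3, e1_kev = 511, e2_kev = 511,
                         dt_ns = 0)
  class(coin) <- c("ppt_coincidences", class(coin))
  geom <- image_geometry(c(21, 21, 21), 1)
  img <- mlem_reconstruct(coin, geom, n_iter = 1, ring = NULL)
  nz <- which(img > 0, arr.ind = TRUE)
  expect_true(all(nz[, 2] == 11 & nz[, 3] == 11))
  expect_equal(nrow(nz), 21)
})

test_that("total intensity is stable across iterations with uniform sensitivity", {
  ring <- detector_ring("preclinical", energy_res_fwhm = 0,
                        timing_fwhm_ps = 0)
  set.seed(29)
  coin <- synthetic_coincidences(matrix(c(0, 0, 0), 1), 400, ring)
  geom <- image_geometry(c(21, 21, 21), 2)
  sums <- sapply(c(2, 4, 8), function(k) {
    sum(mlem_reconstruct(coin, geom, n_iter = k, ring = NULL,
                         sensitivity = "uniform"))
  })
  expect_lt(max(abs(diff(sums))) / sums[1], 1e-3)
})

test_that("two point sources 20 mm apart reconstruct at their positions", {
  ring <- detector_ring("preclinical", energy_res_fwhm = 0,
                        timing_fwhm_ps = 0)
  set.seed(31)
  pts <- rbind(c(-10, 0, 0), c(10, 0, 0))
  coin <- synthetic_coincidences(pts, 1200, ring)
  geom <- image_geometry(c(41, 41, 21), 1)
  img <- mlem_reconstruct(coin, geom, n_iter = 15)
  sl <- img[, 21, 11]  # profile along x through the source plane
  ord <- order(sl, decreasing = TRUE)
  # the two highest well-separated maxima sit at x = -10 and +10 (+-1 voxel)
  top1 <- ord[1]
  top2 <- ord[which(abs(ord - top1) > 5)[1]]
  found <- sort(c(top1, top2))
  expect_true(all(abs(found - c(11, 31)) <= 1))
})

test_that("OSEM with round-robin subsets still converges to the source", {
  ring <- detector_ring("preclinical", energy_res_fwhm = 0,
                        timing_fwhm_ps = 0)
  set.seed(37)
  coin <- synthetic_coincidences(matrix(c(0, 0, 0), 1), 1000, ring)
  geom <- image_geometry(c(31, 31, 31), 1)
  img <- mlem_reconstruct(coin, geom, n_iter = 4, n_subsets = 5)
  mx <- which(img == max(img), arr.ind = TRUE)
  expect_true(all(abs(mx - 16) <= 1))
  expect_error(mlem_reconstruct(coin[0, ], geom), "empty")
})

test_that("TOF weighting localizes along the LOR", {
  ring <- detector_ring("clinical", energy_res_fwhm = 0)
  # single LOR along x with the event at x = +50 mm (dt from flight times)
  d1 <- (ring$radius_mm - 50) / 299.792458
  d2 <- (ring$radius_mm + 50) / 299.792458
  coin <- tibble::tibble(history = 1L, iphi1 = 1L, iz1 = 1L, iphi2 = 1L,
                         iz2 = 1L, x1 = ring$radius_mm, y1 = 0, z1 = 0,
                         x2 = -ring$radius_mm, y2 = 0, z2 = 0,
                         e1_kev = 511, e2_kev = 511, dt_ns = d1 - d2)
  class(coin) <- c("ppt_coincidences", class(coin))
  geom <- image_geometry(c(81, 1, 1), c(2, 2, 2))
  img <- mlem_reconstruct(coin, geom, n_iter = 1, tof = TRUE,
                          tof_fwhm_ps = 214, ring = NULL)
  prof <- as.vector(img)
  expect_equal(which.max(prof), 66, tolerance = 2)  # x = +50 mm -> voxel 66
  expect_lt(prof[11], max(prof) / 10)               # far tail suppressed
})

test_that("postfilter is a sum-preserving Gaussian of the stated width", {
  img <- structure(array(0, dim = c(41, 41, 41)), voxel_mm = rep(1, 3),
                   origin_mm = rep(-20.5, 3), class = "ppt_image3d")
  img[21, 21, 21] <- 100
  expect_identical(postfilter(img, 0), img)
  sm <- postfilter(img, 9)
  expect_equal(sum(sm), 100, tolerance = 1e-6)
  prof <- sm[, 21, 21]
  xs <- seq_len(41) - 21
  half <- max(prof) / 2
  sel <- 21:41
  keep <- prof[sel] > 1e-12
  fwhm <- 2 * stats::approx(rev(prof[sel][keep]), rev(xs[sel][keep]),
                            xout = half)$y
  expect_equal(fwhm, 9, tolerance = 0.5 / 9)
})
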