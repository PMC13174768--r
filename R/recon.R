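#' List-mode MLEM/OSEM reconstruction
#'
#' The system model is a Siddon-style exact ray trace of each line of
#' response (LOR) through the image grid; reconstruction is the standard
#' list-mode expectation-maximization update, optionally accelerated with
#' ordered subsets (round-robin event partition) and optionally weighted
#' along each LOR by a Gaussian time-of-flight kernel centered at the
#' position implied by the coincidence time difference.
#'
#' @name pptsim-recon
NULL

#' Image grid geometry
#'
#' @param shape Voxel counts (nx, ny, nz).
#' @param voxel_mm Voxel size per axis in mm.
#' @return A `ppt_imggeom` list with the grid center at the origin.
#' @export
image_geometry <- function(shape, voxel_mm) {
  shape <- as.integer(rep_len(shape, 3))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  structure(list(shape = shape, voxel_mm = voxel_mm,
                 origin_mm = -shape * voxel_mm / 2), class = "ppt_imggeom")
}

#' Exact voxel traversal of a chord (Siddon ray tracing)
#'
#' @param geom An [image_geometry()] (or a `ppt_phantom`, whose grid is
#'   used).
#' @param p1,p2 Numeric length-3 endpoints in mm.
#' @return A tibble with `voxel` (linear index, column-major), `length_mm`
#'   (intersection length); lengths sum to the chord length inside the grid.
#'   A degenerate zero-length LOR yields an empty path.
#' @export
lor_path <- function(geom, p1, p2) {
  g <- if (inherits(geom, "ppt_phantom"))
    image_geometry(geom$shape, geom$voxel_mm) else geom
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  if (L < 1e-12) {
    return(tibble::tibble(voxel = integer(), length_mm = numeric()))
  }
  lo <- g$origin_mm; hi <- g$origin_mm + g$shape * g$voxel_mm
  # entry/exit parameters of the grid box
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) {
      if (p1[ax] < lo[ax] || p1[ax] > hi[ax]) {
        return(tibble::tibble(voxel = integer(), length_mm = numeric()))
      }
    } else {
      ta <- (lo[ax] - p1[ax]) / d[ax]; tb <- (hi[ax] - p1[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) {
    return(tibble::tibble(voxel = integer(), length_mm = numeric()))
  }
  # all plane crossings between t0 and t1
  ts <- c(t0, t1)
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) next
    planes <- lo[ax] + (0:g$shape[ax]) * g$voxel_mm[ax]
    tt <- (planes - p1[ax]) / d[ax]
    ts <- c(ts, tt[tt > t0 & tt < t1])
  }
  ts <- sort(unique(ts))
  tm <- (ts[-1] + ts[-length(ts)]) / 2
  seg <- (ts[-1] - ts[-length(ts)]) * L
  mx <- cbind(p1[1] + tm * d[1], p1[2] + tm * d[2], p1[3] + tm * d[3])
  i <- pmin(g$shape[1], pmax(1, floor((mx[, 1] - lo[1]) / g$voxel_mm[1]) + 1))
  j <- pmin(g$shape[2], pmax(1, floor((mx[, 2] - lo[2]) / g$voxel_mm[2]) + 1))
  k <- pmin(g$shape[3], pmax(1, floor((mx[, 3] - lo[3]) / g$voxel_mm[3]) + 1))
  vox <- as.integer(i + (j - 1) * g$shape[1] + (k - 1) * g$shape[1] * g$shape[2])
  keep <- seg > 1e-12
  tibble::tibble(voxel = vox[keep], length_mm = seg[keep],
                 t_mid = tm[keep])[, c("voxel", "length_mm", "t_mid")]
}

# sparse system matrix (events x voxels) with optional TOF row weighting
.ppt_system_matrix <- function(coin, g, tof = FALSE, tof_fwhm_ps = 214) {
  n_ev <- nrow(coin)
  nvox <- prod(g$shape)
  ii <- vector("list", n_ev); jj <- vector("list", n_ev)
  xx <- vector("list", n_ev)
  sigma_mm <- .ppt_c_mm_ns * (tof_fwhm_ps / 1000) / (2 * sqrt(2 * log(2))) / 2
  for (e in seq_len(n_ev)) {
    p1 <- c(coin$x1[e], coin$y1[e], coin$z1[e])
    p2 <- c(coin$x2[e], coin$y2[e], coin$z2[e])
    path <- lor_path(g, p1, p2)
    if (!nrow(path)) next
    w <- path$length_mm
    if (tof) {
      L <- sqrt(sum((p2 - p1)^2))
      # implied annihilation position: midpoint + u * c*dt/2 (u from 1 to 2)
      t_imp <- 0.5 + .ppt_c_mm_ns * coin$dt_ns[e] / 2 / L
      w <- w * exp(-((path$t_mid - t_imp) * L)^2 / (2 * sigma_mm^2))
    }
    keep <- w > 0
    ii[[e]] <- rep.int(e, sum(keep))
    jj[[e]] <- path$voxel[keep]
    xx[[e]] <- w[keep]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n_ev, nvox))
}

# geometric sensitivity image: per-voxel fraction of isotropic emission
# axes whose both photons intersect the ring inside the axial extent,
# integrated over a deterministic spherical Fibonacci direction set
.ppt_sensitivity <- function(g, ring, n_dirs = 400) {
  cx <- g$origin_mm[1] + (seq_len(g$shape[1]) - 0.5) * g$voxel_mm[1]
  cy <- g$origin_mm[2] + (seq_len(g$shape[2]) - 0.5) * g$voxel_mm[2]
  cz <- g$origin_mm[3] + (seq_len(g$shape[3]) - 0.5) * g$voxel_mm[3]
  gg <- expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE)
  x <- gg$x; y <- gg$y; z <- gg$z
  i <- seq_len(n_dirs)
  w3 <- 1 - (2 * i - 1) / n_dirs
  phi <- i * pi * (3 - sqrt(5))
  st <- sqrt(pmax(0, 1 - w3^2))
  dirs <- cbind(st * cos(phi), st * sin(phi), w3)
  R2 <- ring$radius_mm^2
  half <- ring$axial_mm / 2
  sens <- numeric(length(x))
  r2 <- x^2 + y^2
  for (k in i) {
    d <- dirs[k, ]
    a <- d[1]^2 + d[2]^2
    if (a < 1e-9) next  # axis-parallel axis misses the ring both ways
    b <- x * d[1] + y * d[2]
    disc <- sqrt(pmax(0, b^2 - a * (r2 - R2)))
    tp <- (-b + disc) / a
    tm <- (b + disc) / a
    ok <- abs(z + d[3] * tp) <= half & abs(z - d[3] * tm) <= half
    sens[ok] <- sens[ok] + 1
  }
  sens / n_dirs
}

#' List-mode MLEM/OSEM reconstruction
#'
#' @param coincidences A `ppt_coincidences` tibble (nonempty). LOR
#'   endpoints are the recorded crystal centers.
#' @param geom An [image_geometry()] for the output image.
#' @param n_iter Number of full iterations (>= 1).
#' @param n_subsets Ordered subsets (1 = plain MLEM); events are partitioned
#'   round-robin.
#' @param tof Use the coincidence time differences to weight voxels along
#'   each LOR with a Gaussian kernel.
#' @param tof_fwhm_ps Timing resolution FWHM (ps) defining the TOF kernel.
#' @param ring The [detector_ring()] defining the geometric sensitivity;
#'   defaults to the ring recorded by [sort_coincidences()].
#' @param sensitivity Sensitivity image override: `NULL` (geometric ring
#'   acceptance when a ring is available, otherwise uniform over the
#'   covered voxels), `"uniform"`, or a numeric vector of length
#'   `prod(shape)`.
#' @return A `ppt_image3d`: 3D array of nonnegative intensities with
#'   `voxel_mm` and `origin_mm` attributes.
#' @export
mlem_reconstruct <- function(coincidences, geom, n_iter = 10, n_subsets = 1,
                             tof = FALSE, tof_fwhm_ps = 214,
                             ring = attr(coincidences, "ring"),
                             sensitivity = NULL) {
  stopifnot(n_iter >= 1, n_subsets >= 1)
  if (!nrow(coincidences)) {
    stop("empty coincidence list", call. = FALSE)
  }
  g <- if (inherits(geom, "ppt_phantom"))
    image_geometry(geom$shape, geom$voxel_mm) else geom
  A <- .ppt_system_matrix(coincidences, g, tof = tof,
                          tof_fwhm_ps = tof_fwhm_ps)
  rs <- Matrix::rowSums(A)
  A <- A[rs > 0, , drop = FALSE]
  n_ev <- nrow(A)
  nvox <- prod(g$shape)
  sens <- if (is.numeric(sensitivity)) sensitivity
          else if (identical(sensitivity, "uniform")) rep(1, nvox)
          else if (!is.null(ring)) .ppt_sensitivity(g, ring)
          else rep(1, nvox)
  # voxels never seen by any LOR are excluded from updates
  seen <- as.numeric(Matrix::colSums(A)) > 0
  upd <- sens > 0 & seen
  x <- rep(1, nvox)
  x[!upd] <- 0
  subset_of <- (seq_len(n_ev) - 1L) %% n_subsets + 1L
  for (it in seq_len(n_iter)) {
    for (s in seq_len(n_subsets)) {
      rows <- which(subset_of == s)
      As <- A[rows, , drop = FALSE]
      q <- as.numeric(As %*% x)
      q[q <= 0] <- Inf
      bp <- as.numeric(Matrix::crossprod(As, 1 / q))
      ssub <- sens / n_subsets
      x[upd] <- x[upd] * bp[upd] / ssub[upd]
    }
  }
  img <- array(x, dim = g$shape)
  structure(img, voxel_mm = g$voxel_mm, origin_mm = g$origin_mm,
            class = "ppt_image3d")
}

#' Gaussian post-reconstruction filter
#'
#' Separable Gaussian convolution with reflective boundaries; the total
#' image intensity is preserved.
#'
#' @param image A `ppt_image3d` (or plain 3D array with a `voxel_mm`
#'   attribute).
#' @param fwhm_mm Filter FWHM in mm (0 = identity).
#' @return The filtered `ppt_image3d`.
#' @export
postfilter <- function(image, fwhm_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(image)
  v <- attr(image, "voxel_mm")
  out <- unclass(image)
  dims <- dim(out)
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / v[ax]
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    out <- .ppt_convolve_axis(out, k, ax)
  }
  structure(out, voxel_mm = v, origin_mm = attr(image, "origin_mm"),
            dim = dims, class = "ppt_image3d")
}

# 1D convolution along one axis with reflective padding
.ppt_convolve_axis <- function(arr, k, ax) {
  half <- (length(k) - 1L) / 2L
  n <- dim(arr)[ax]
  idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half))
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  dm <- dim(a)
  m <- matrix(a, nrow = dm[1])
  mp <- m[idx, , drop = FALSE]
  res <- matrix(0, nrow = n, ncol = ncol(m))
  for (o in seq_along(k)) {
    res <- res + k[o] * mp[(o - 1) + seq_len(n), , drop = FALSE]
  }
  a <- array(res, dim = dm)
  aperm(a, order(perm))
}

#' @export
print.ppt_image3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ppt_image3d> %d x %d x %d voxels of %s mm, total %.4g\n",
              d[1], d[2], d[3],
              paste(attr(x, "voxel_mm"), collapse = " x "), sum(x)))
  invisible(x)
}

#' Tidy an image into a voxel table
#'
#' @param x A `ppt_image3d`.
#' @param ... Unused.
#' @return A tibble with voxel centers `x`, `y`, `z` (mm) and `value`.
#' @method tidy ppt_image3d
#' @export
tidy.ppt_image3d <- function(x, ...) {
  d <- dim(x); v <- attr(x, "voxel_mm"); o <- attr(x, "origin_mm")
  val <- as.vector(unclass(x))
  cx <- o[1] + (seq_len(d[1]) - 0.5) * v[1]
  cy <- o[2] + (seq_len(d[2]) - 0.5) * v[2]
  cz <- o[3] + (seq_len(d[3]) - 0.5) * v[3]
  g <- expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(x = g$x, y = g$y, z = g$z, value = val)
}

#' Write an image as NIfTI
#'
#' @param image A `ppt_image3d`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(image, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export", call. = FALSE)
  }
  img <- RNifti::asNifti(unclass(image), pixdim = attr(image, "voxel_mm"))
  RNifti::writeNifti(img, path)
  invisible(path)
}
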