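# Geometric descriptors (features 1-15): region ratios, ellipse-based shape
# measures, fold symmetry, hand-mirror proportion, box-counting fractal
# dimension and contour-distance moments.
#
# Pixel coordinates are (row, col), 0-based, pixel centres at integer
# positions; the ellipse fit uses second-order central moments.

# Region centroid and 2x2 central-moment (covariance) matrix of a mask.
mask_moments <- function(mask) {
  idx <- which(mask)
  n <- length(idx)
  if (n == 0) stop("empty mask")
  H <- nrow(mask)
  r <- (idx - 1) %% H
  c <- (idx - 1) %/% H
  ctr <- c(mean(r), mean(c))
  dr <- r - ctr[1]; dc <- c - ctr[2]
  list(n = n, centroid = ctr,
       cov = matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)),
                    2, 2))
}

#' Fit an ellipse to a binary mask by second-order central moments
#'
#' The semi-axes are those of the ellipse with the same normalized second
#' central moments as the region (`2 * sqrt(eigenvalue)`), so a disc of
#' radius r yields `a = b = r`.
#'
#' @param mask logical matrix.
#' @return object of class `ellipse_fit` with `centroid` (row, col, 0-based),
#'   `semimajor_a`, `semiminor_b` (pixels) and `orientation` (radians of the
#'   major axis in (row, col) space).
#' @export
ellipse_fit <- function(mask) {
  mm <- mask_moments(mask)
  ev <- eigen(mm$cov, symmetric = TRUE)
  a <- 2 * sqrt(max(ev$values[1], 0))
  b <- 2 * sqrt(max(ev$values[2], 1e-12))
  if (a <= 0 || b <= 0) stop("degenerate mask: zero-extent ellipse fit")
  u <- ev$vectors[, 1]
  structure(
    list(centroid = mm$centroid, semimajor_a = a, semiminor_b = b,
         orientation = atan2(u[2], u[1])),
    class = "ellipse_fit"
  )
}

#' Trace the ordered outer boundary of a mask
#'
#' Uses Moore-neighbour tracing (via EBImage) on the largest connected
#' component; consecutive points are 8-connected and the trace is closed.
#'
#' @param mask logical matrix.
#' @return object of class `contour_trace`: `points` (n x 2 matrix of
#'   (row, col), 0-based, in boundary order) and `centroid` of the region.
#' @export
contour_trace <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  if (length(oc) == 0) stop("empty mask")
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]]
  if (nrow(pts) < 8) stop("contour shorter than 8 points")
  structure(
    list(points = pts, centroid = mask_moments(mask)$centroid),
    class = "contour_trace"
  )
}

# Crofton-style chain perimeter: unit steps count 1, diagonal steps sqrt(2).
contour_perimeter <- function(trace) {
  p <- trace$points
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  step <- abs(q - p)
  sum(ifelse(step[, 1] + step[, 2] == 2, sqrt(2), pmax(step[, 1], step[, 2])))
}

# Inner boundary: mask pixels with at least one 4-neighbour of background
# (the image border counts as background).
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(core & !nb, arr.ind = TRUE) - 1L
}

#' Region geometry features (1-5)
#'
#' Computes, for one sample: the nucleus/cytoplasm pixel-area ratio, the
#' nucleus form factor (area / perimeter, taken literally from the feature
#' table; the conventional dimensionless `4*pi*area/perimeter^2` is available
#' via `conventional_form_factor = TRUE`), roundness
#' `4*area/(pi*major_axis^2)`, eccentricity as the major/minor axis ratio,
#' and compactness `perimeter^2/area`.
#'
#' @param sample a [labeled_sample()].
#' @param conventional_form_factor use `4*pi*A/P^2` instead of `A/P`.
#' @return named numeric vector of length 5.
#' @export
region_geometry <- function(sample, conventional_form_factor = FALSE) {
  n_area <- sum(sample$nucleus_mask)
  c_area <- sum(sample$cell_mask & !sample$nucleus_mask)
  if (c_area == 0) stop("degenerate sample: empty cytoplasm")
  ef <- ellipse_fit(sample$nucleus_mask)
  per <- contour_perimeter(contour_trace(sample$nucleus_mask))
  ff <- if (conventional_form_factor) 4 * pi * n_area / per^2 else n_area / per
  c(
    nc_ratio = n_area / c_area,
    form_factor = ff,
    roundness = 4 * n_area / (pi * (2 * ef$semimajor_a)^2),
    eccentricity = ef$semimajor_a / ef$semiminor_b,
    compactness = per^2 / n_area
  )
}

#' Shape symmetry about the nucleus major axis (feature 6)
#'
#' Folds the mask across the line through its centroid along the fitted
#' major axis: the half on the negative side of the axis is reflected onto
#' the positive side, and the returned value is
#' `overlap area / larger half area`, in `(0, 1]`; values near 1 indicate a
#' mirror-symmetric nucleus.
#'
#' @param nucleus_mask logical matrix.
#' @return symmetry value in `(0, 1]`.
#' @export
shape_symmetry <- function(nucleus_mask) {
  idx <- which(nucleus_mask)
  H <- nrow(nucleus_mask); W <- ncol(nucleus_mask)
  r <- (idx - 1) %% H
  c <- (idx - 1) %/% H
  if (length(unique(r)) < 2 || length(unique(c)) < 2) {
    stop("degenerate mask: single row or column")
  }
  ef <- ellipse_fit(nucleus_mask)
  u <- c(cos(ef$orientation), sin(ef$orientation))
  nrm <- c(-u[2], u[1])
  d <- (r - ef$centroid[1]) * nrm[1] + (c - ef$centroid[2]) * nrm[2]
  h1 <- d >= 0
  n1 <- sum(h1); n2 <- sum(!h1)
  if (n2 == 0 || n1 == 0) return(0)
  # reflect the negative half across the axis and count landings on the
  # positive half of the mask
  rr <- round(r[!h1] - 2 * d[!h1] * nrm[1])
  rc <- round(c[!h1] - 2 * d[!h1] * nrm[2])
  ok <- rr >= 0 & rr < H & rc >= 0 & rc < W
  pos_half <- matrix(FALSE, H, W)
  pos_half[idx[h1]] <- TRUE
  part1 <- sum(pos_half[cbind(rr[ok] + 1, rc[ok] + 1)])
  part1 / max(n1, n2)
}

#' Hand-mirror proportion (feature 7)
#'
#' Fits an ellipse to the nucleus (semi-axes `a >= b`) and takes `c` as the
#' maximum Euclidean distance from the nucleus centroid to a cell-contour
#' point lying outside the fitted ellipse (falling back to all contour
#' points when none lies outside, as for a cell identical to its nucleus).
#' Returns `(a + c) / (b + c)`.
#'
#' @param sample a [labeled_sample()].
#' @return proportion `>= 1` up to rasterization noise.
#' @export
hand_mirror_ratio <- function(sample) {
  ef <- ellipse_fit(sample$nucleus_mask)
  tr <- contour_trace(sample$cell_mask)
  dr <- tr$points[, 1] - ef$centroid[1]
  dc <- tr$points[, 2] - ef$centroid[2]
  uu <- dr * cos(ef$orientation) + dc * sin(ef$orientation)
  vv <- -dr * sin(ef$orientation) + dc * cos(ef$orientation)
  outside <- (uu / ef$semimajor_a)^2 + (vv / ef$semiminor_b)^2 > 1
  dist <- sqrt(dr^2 + dc^2)
  cc <- if (any(outside)) max(dist[outside]) else max(dist)
  (ef$semimajor_a + cc) / (ef$semiminor_b + cc)
}

#' Box-counting fractal dimension of a mask boundary (features 8, 12)
#'
#' Counts occupied boxes over the boundary pixel set at box sizes
#' 2, 4, 8, 16, 32, 64 and returns the least-squares slope of
#' `log(count)` against `log(1/size)`; near 1 for smooth curves, larger for
#' rough ones.
#'
#' @param mask logical matrix.
#' @param box_sizes box side lengths in pixels.
#' @return dimension estimate (dimensionless).
#' @export
fractal_dimension <- function(mask, box_sizes = c(2, 4, 8, 16, 32, 64)) {
  bp <- boundary_pixels(mask)
  if (nrow(bp) < 8) stop("boundary shorter than 8 pixels")
  counts <- vapply(box_sizes, function(s) {
    nrow(unique(cbind(bp[, 1] %/% s, bp[, 2] %/% s)))
  }, 0)
  x <- log(1 / box_sizes)
  unname(stats::coef(stats::lm(log(counts) ~ x))[2])
}

# Population moment statistics of a numeric vector; degenerate (zero
# variance) input gets skewness 0 and kurtosis 1.
moment_stats <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) {
    return(c(mean = m, var = 0, sd = 0, skew = 0, kurt = 1))
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(mean = m, var = v, sd = sqrt(v), skew = m3 / v^1.5, kurt = m4 / v^2)
}

#' Contour-distance moments (features 9-11 / 13-15)
#'
#' Distances from the region centroid to the ordered boundary points;
#' returns their population variance, Fisher skewness and (non-excess)
#' kurtosis.
#'
#' @param trace a [contour_trace()].
#' @return named numeric vector `(variance, skewness, kurtosis)`.
#' @export
contour_moments <- function(trace) {
  stopifnot(inherits(trace, "contour_trace"))
  if (nrow(trace$points) < 8) stop("fewer than 8 contour points")
  d <- sqrt((trace$points[, 1] - trace$centroid[1])^2 +
            (trace$points[, 2] - trace$centroid[2])^2)
  ms <- moment_stats(d)
  c(variance = unname(ms["var"]), skewness = unname(ms["skew"]),
    kurtosis = unname(ms["kurt"]))
}
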