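# Texture descriptors (features 16-34): Haar wavelet statistics, Haralick
# co-occurrence statistics and Fourier-magnitude statistics, all computed on
# the grayscale nucleus bounding-box patch. Pixels inside the bounding box
# but outside the nucleus mask are filled with the mean nucleus intensity so
# that background never leaks into the texture statistics.

# ITU-R BT.601 luma weights.
to_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Grayscale nucleus bounding-box patch, mask-filled (values in [0, 255]).
nucleus_patch <- function(sample) {
  idx <- which(sample$nucleus_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty nucleus mask")
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  g <- to_gray(sample$image)[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  m <- sample$nucleus_mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  g[!m] <- mean(g[m])
  g
}

# One orthonormal 2D Haar analysis step. The "horizontal" detail H is the
# high-pass along the column (left-right) axis with low-pass along rows, so
# an intensity step running vertically loads H, not V.
haar_step <- function(x) {
  H <- 2 * (nrow(x) %/% 2); W <- 2 * (ncol(x) %/% 2)
  x <- x[seq_len(H), seq_len(W), drop = FALSE]
  oc <- seq(1, W, by = 2)
  lc <- (x[, oc, drop = FALSE] + x[, oc + 1, drop = FALSE]) / sqrt(2)
  hc <- (x[, oc, drop = FALSE] - x[, oc + 1, drop = FALSE]) / sqrt(2)
  or <- seq(1, H, by = 2)
  list(
    A = (lc[or, , drop = FALSE] + lc[or + 1, , drop = FALSE]) / sqrt(2),
    V = (lc[or, , drop = FALSE] - lc[or + 1, , drop = FALSE]) / sqrt(2),
    H = (hc[or, , drop = FALSE] + hc[or + 1, , drop = FALSE]) / sqrt(2),
    D = (hc[or, , drop = FALSE] - hc[or + 1, , drop = FALSE]) / sqrt(2)
  )
}

#' Haar wavelet statistics (features 16-21)
#'
#' Level-`level` orthonormal 2D Haar decomposition of the grayscale nucleus
#' patch; returns the mean and population variance of the approximation
#' (`A`), horizontal-detail (`H`) and vertical-detail (`V`) coefficient
#' arrays at the final level. A constant patch of value v has `A` mean
#' `2^level * v` and zero detail.
#'
#' @param sample a [labeled_sample()].
#' @param level decomposition level (default 1).
#' @return named numeric vector of length 6.
#' @export
haar_features <- function(sample, level = 1) {
  x <- nucleus_patch(sample)
  if (min(dim(x)) < 2^level) {
    stop("nucleus patch smaller than 2^level in one dimension")
  }
  for (i in seq_len(level)) {
    dec <- haar_step(x)
    x <- dec$A
  }
  c(
    haar_mean_A = mean(dec$A), haar_mean_H = mean(dec$H),
    haar_mean_V = mean(dec$V),
    haar_var_A = mean((dec$A - mean(dec$A))^2),
    haar_var_H = mean((dec$H - mean(dec$H))^2),
    haar_var_V = mean((dec$V - mean(dec$V))^2)
  )
}

# Symmetric, normalized gray-level co-occurrence matrix for one (dr, dc)
# offset, over `levels` gray levels (quantized values in 0..levels-1).
glcm_one <- function(q, dr, dc, levels) {
  H <- nrow(q); W <- ncol(q)
  r1 <- max(1, 1 - dr):min(H, H - dr)
  c1 <- max(1, 1 - dc):min(W, W - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  tab <- unname(unclass(table(factor(a, levels = 0:(levels - 1)),
                               factor(b, levels = 0:(levels - 1)))))
  m <- tab + t(tab)
  m / sum(m)
}

#' Haralick texture statistics (features 22-26)
#'
#' The grayscale nucleus patch is quantized to `levels` equal-width bins
#' over `[0, 255]`; the symmetric normalized co-occurrence matrix at
#' distance 1 is averaged over the four directions (0, 45, 90, 135 degrees)
#' and summarized as contrast, correlation, homogeneity, energy and entropy
#' (base-2, with `0 * log(0) = 0`). Correlation of a single-level patch is
#' defined as 0.
#'
#' @param sample a [labeled_sample()].
#' @param levels number of gray levels (default 8).
#' @return named numeric vector of length 5.
#' @export
haralick_features <- function(sample, levels = 8) {
  g <- nucleus_patch(sample)
  if (min(dim(g)) < 2) stop("degenerate nucleus patch")
  q <- pmin(floor(g / (256 / levels)), levels - 1)
  offs <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  p <- Reduce(`+`, lapply(offs, function(o) glcm_one(q, o[1], o[2], levels))) / 4
  glcm_stats(p)
}

# The five summary statistics of a normalized co-occurrence matrix.
glcm_stats <- function(p) {
  levels <- nrow(p)
  i <- matrix(0:(levels - 1), levels, levels)
  j <- t(i)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  sd_i <- sqrt(sum(p * (i - mu_i)^2)); sd_j <- sqrt(sum(p * (j - mu_j)^2))
  corr <- if (sd_i * sd_j > 0) {
    sum(p * (i - mu_i) * (j - mu_j)) / (sd_i * sd_j)
  } else 0
  nz <- p > 0
  c(
    glcm_contrast = sum(p * (i - j)^2),
    glcm_correlation = corr,
    glcm_homogeneity = sum(p / (1 + abs(i - j))),
    glcm_energy = sum(p^2),
    glcm_entropy = -sum(p[nz] * log2(p[nz]))
  )
}

#' Fourier-magnitude statistics (features 27-34)
#'
#' Forward branch: mean, population standard deviation, skewness and
#' (non-excess) kurtosis of the magnitude spectrum of the unnormalized 2D
#' DFT of the grayscale nucleus patch, DC included. Inverse branch: the same
#' four statistics of the magnitude of the `1/N^2`-normalized inverse DFT
#' applied to the magnitude-only spectrum (phase discarded).
#'
#' @param sample a [labeled_sample()].
#' @return named numeric vector of length 8.
#' @export
fourier_features <- function(sample) {
  g <- nucleus_patch(sample)
  if (length(g) < 2) stop("degenerate nucleus patch")
  M <- Mod(stats::fft(g))
  fwd <- moment_stats(as.vector(M))
  Mi <- Mod(stats::fft(M, inverse = TRUE) / length(M))
  inv <- moment_stats(as.vector(Mi))
  c(
    fft_mean = unname(fwd["mean"]), fft_sd = unname(fwd["sd"]),
    fft_skew = unname(fwd["skew"]), fft_kurt = unname(fwd["kurt"]),
    ifft_mean = unname(inv["mean"]), ifft_sd = unname(inv["sd"]),
    ifft_skew = unname(inv["skew"]), ifft_kurt = unname(inv["kurt"])
  )
}
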