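test_that("Haar statistics: constant patch, oriented step edge, rotation symmetry", {
  s <- patch_sample(matrix(120, 16, 16))
  h <- haar_features(s)
  expect_equal(h[["haar_mean_A"]], 2 * 120, tolerance = 1e-9)
  expect_equal(h[["haar_mean_H"]], 0, tolerance = 1e-9)
  expect_equal(h[["haar_mean_V"]], 0, tolerance = 1e-9)
  expect_equal(unname(h[4:6]), c(0, 0, 0), tolerance = 1e-9)
  # level 2 doubles the approximation gain: mean(A_2) = 4 * value
  h2 <- haar_features(s, level = 2)
  expect_equal(h2[["haar_mean_A"]], 4 * 120, tolerance = 1e-9)

  # vertical step edge (intensity changes along the horizontal axis) loads
  # the horizontal-detail band; checked against a direct 8x8 transform.
  # The edge sits inside a column pair so the detail filter straddles it.
  step <- cbind(matrix(20, 8, 3), matrix(220, 8, 5))
  hs <- haar_features(patch_sample(step))
  expect_gt(hs[["haar_var_H"]], hs[["haar_var_V"]])
  # direct orthonormal transform on the 8x8 patch
  lc <- (step[, c(1, 3, 5, 7)] + step[, c(2, 4, 6, 8)]) / sqrt(2)
  hc <- (step[, c(1, 3, 5, 7)] - step[, c(2, 4, 6, 8)]) / sqrt(2)
  or <- c(1, 3, 5, 7)
  A <- (lc[or, ] + lc[or + 1, ]) / sqrt(2)
  H <- (hc[or, ] + hc[or + 1, ]) / sqrt(2)
  V <- (lc[or, ] - lc[or + 1, ]) / sqrt(2)
  expect_equal(hs[["haar_mean_A"]], mean(A), tolerance = 1e-9)
  expect_equal(hs[["haar_mean_H"]], mean(H), tolerance = 1e-9)
  expect_equal(hs[["haar_var_H"]], mean((H - mean(H))^2), tolerance = 1e-9)
  expect_equal(hs[["haar_var_V"]], mean((V - mean(V))^2), tolerance = 1e-9)

  # a patch and its 180-degree rotation have identical variances
  set.seed(4)
  p <- matrix(runif(64, 0, 255), 8, 8)
  v1 <- haar_features(patch_sample(p))[4:6]
  v2 <- haar_features(patch_sample(p[8:1, 8:1]))[4:6]
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("Haralick statistics: constant patch and checkerboard pair-count oracle", {
  s <- patch_sample(matrix(100, 12, 12))
  f <- haralick_features(s)
  expect_equal(f[["glcm_contrast"]], 0, tolerance = 1e-12)
  expect_equal(f[["glcm_homogeneity"]], 1, tolerance = 1e-12)
  expect_equal(f[["glcm_energy"]], 1, tolerance = 1e-12)
  expect_equal(f[["glcm_entropy"]], 0, tolerance = 1e-12)
  expect_equal(f[["glcm_correlation"]], 0)  # degenerate: defined as 0

  # 2-level checkerboard, horizontal offset only: exhaustive enumeration of
  # all horizontal pixel pairs on the 4x4 board
  board <- matrix(c(0, 7, 0, 7, 7, 0, 7, 0, 0, 7, 0, 7, 7, 0, 7, 0), 4, 4)
  q <- board  # already quantized levels 0 and 7
  p_pkg <- blastclass:::glcm_one(q, 0, 1, 8)
  pairs <- matrix(0, 8, 8)
  for (r in 1:4) for (cc in 1:3) {
    a <- q[r, cc] + 1; b <- q[r, cc + 1] + 1
    pairs[a, b] <- pairs[a, b] + 1
    pairs[b, a] <- pairs[b, a] + 1
  }
  pairs <- pairs / sum(pairs)
  expect_equal(unclass(p_pkg), pairs, tolerance = 1e-12)
  ii <- matrix(0:7, 8, 8); jj <- t(ii)
  expect_equal(sum(p_pkg * (ii - jj)^2), sum(pairs * (ii - jj)^2),
               tolerance = 1e-12)

  # bounds on arbitrary patches
  set.seed(7)
  for (i in 1:3) {
    f2 <- haralick_features(patch_sample(matrix(runif(100, 0, 255), 10, 10)))
    expect_gt(f2[["glcm_energy"]], 0)
    expect_lte(f2[["glcm_energy"]], 1)
    expect_gte(f2[["glcm_entropy"]], 0)
    expect_lte(f2[["glcm_entropy"]], 2 * log2(8))
  }
})

test_that("Fourier statistics match a naive double-sum DFT oracle to 1e-9", {
  set.seed(11)
  patch <- matrix(sample(0:255, 16), 4, 4)
  f <- fourier_features(patch_sample(patch))
  # O(N^4) direct DFT
  N <- 4
  Fm <- matrix(0 + 0i, N, N)
  for (u in 0:(N - 1)) for (v in 0:(N - 1)) {
    acc <- 0 + 0i
    for (x in 0:(N - 1)) for (y in 0:(N - 1)) {
      acc <- acc + patch[x + 1, y + 1] * exp(-2i * pi * (u * x / N + v * y / N))
    }
    Fm[u + 1, v + 1] <- acc
  }
  M <- Mod(Fm)
  # inverse applied to the magnitude-only spectrum, 1/N^2 normalization
  G <- matrix(0 + 0i, N, N)
  for (x in 0:(N - 1)) for (y in 0:(N - 1)) {
    acc <- 0 + 0i
    for (u in 0:(N - 1)) for (v in 0:(N - 1)) {
      acc <- acc + M[u + 1, v + 1] * exp(2i * pi * (u * x / N + v * y / N))
    }
    G[x + 1, y + 1] <- acc / N^2
  }
  stat4 <- function(x) {
    mu <- mean(x); m2 <- mean((x - mu)^2)
    c(mu, sqrt(m2), mean((x - mu)^3) / m2^1.5, mean((x - mu)^4) / m2^2)
  }
  expect_equal(unname(f[1:4]), stat4(as.vector(M)), tolerance = 1e-9)
  expect_equal(unname(f[5:8]), stat4(as.vector(Mod(G))), tolerance = 1e-9)
})

test_that("Fourier statistics: DC-only constant patch and shift invariance", {
  v <- 77
  f <- fourier_features(patch_sample(matrix(v, 8, 8)))
  # single nonzero component DC = N^2 v; mean of magnitudes = v
  expect_equal(f[["fft_mean"]], v, tolerance = 1e-9)
  set.seed(3)
  p <- matrix(runif(64, 0, 255), 8, 8)
  shifted <- p[c(4:8, 1:3), c(7:8, 1:6)]
  f1 <- fourier_features(patch_sample(p))[1:4]
  f2 <- fourier_features(patch_sample(shifted))[1:4]
  expect_equal(f1, f2, tolerance = 1e-9)
})
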