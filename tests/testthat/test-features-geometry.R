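test_that("region geometry matches analytic values on rasterized discs", {
  s <- disc_sample(S = 256, r_cell = 80, r_nuc = 40)
  g <- region_geometry(s)
  # N/C for nucleus r=40 in cell r=80: 1/(4-1) = 1/3, rasterization tol 5%
  expect_lt(abs(g[["nc_ratio"]] / (1 / 3) - 1), 0.05)
  expect_lt(abs(g[["roundness"]] - 1), 0.05)
  expect_lt(abs(g[["eccentricity"]] - 1), 0.02)
  # form factor is area/perimeter (literal definition): pi r^2 / (2 pi r) = r/2
  expect_lt(abs(g[["form_factor"]] / 20 - 1), 0.1)
  # conventional variant is ~1 for a circle
  g2 <- region_geometry(s, conventional_form_factor = TRUE)
  expect_lt(abs(g2[["form_factor"]] - 1), 0.15)
  # compactness of a circle ~ 4 pi^2 r^2 / (pi r^2) = 4 pi
  expect_lt(abs(g2[["compactness"]] / (4 * pi) - 1), 0.15)
})

test_that("eccentricity of a 2:1 ellipse is 2, against a moments oracle", {
  nuc <- ellipse_mask(256, 128, 128, 60, 30, phi = 0.4)
  s <- mask_sample(nuc)
  g <- region_geometry(s)
  expect_lt(abs(g[["eccentricity"]] - 2), 0.05)
  # oracle: axis lengths from eigenvalues of the raw pixel covariance
  idx <- which(nuc, arr.ind = TRUE)
  ev <- eigen(cov(idx) * (nrow(idx) - 1) / nrow(idx))$values
  expect_lt(abs(g[["eccentricity"]] - sqrt(ev[1] / ev[2])), 1e-6)
})

test_that("empty cytoplasm is a degenerate-sample error", {
  m <- disc_mask(64, 32, 32, 20)
  img <- flat_image(64)
  s <- labeled_sample(img, m, m, "pre_T")
  expect_error(region_geometry(s), "empty cytoplasm")
  expect_error(color_features(s), "empty cytoplasm")
})

test_that("shape symmetry is ~1 for mirror-symmetric masks", {
  expect_gt(shape_symmetry(disc_mask(128, 64, 64, 40)), 0.95)
  expect_gt(shape_symmetry(ellipse_mask(128, 64, 64, 50, 25, phi = 0)), 0.95)
  expect_gt(shape_symmetry(ellipse_mask(128, 64, 64, 50, 25, phi = 1.1)), 0.95)
})

test_that("symmetry of a quarter-removed disc matches a brute-force fold oracle", {
  S <- 128
  m <- disc_mask(S, 64, 64, 40)
  rows <- matrix(seq_len(S) - 0.5, S, S)
  cols <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
  m[rows > 64 & cols > 64] <- FALSE   # remove one quarter
  val <- shape_symmetry(m)
  # brute-force oracle: per-pixel reflect-and-intersect across the fitted
  # major axis (independent loop implementation)
  ef <- ellipse_fit(m)
  u <- c(cos(ef$orientation), sin(ef$orientation))
  nrm <- c(-u[2], u[1])
  pts <- which(m, arr.ind = TRUE) - 1L
  d <- (pts[, 1] - ef$centroid[1]) * nrm[1] + (pts[, 2] - ef$centroid[2]) * nrm[2]
  pos <- pts[d >= 0, , drop = FALSE]
  neg <- pts[d < 0, , drop = FALSE]
  pos_set <- paste(pos[, 1], pos[, 2])
  hits <- 0
  for (i in seq_len(nrow(neg))) {
    di <- d[d < 0][i]
    ref <- round(neg[i, ] - 2 * di * nrm)
    if (paste(ref[1], ref[2]) %in% pos_set) hits <- hits + 1
  }
  oracle <- hits / max(nrow(pos), nrow(neg))
  expect_equal(val, oracle, tolerance = 1e-12)
  expect_lt(val, 0.8)  # clearly below the symmetric case
})

test_that("hand-mirror ratio: circle limit and constructed elongated case", {
  # cell identical to a circular nucleus: a = b = c = r -> ratio 1
  m <- disc_mask(128, 64, 64, 40)
  s <- mask_sample(m, cell = m)
  expect_lt(abs(hand_mirror_ratio(s) - 1), 0.05)

  # elongated nucleus a = 2b with cell contour at distance ~2b outside the
  # ellipse: ratio -> (2b + c)/(b + c) with c measured by brute force
  S <- 256
  nuc <- ellipse_mask(S, 128, 128, 60, 30, phi = 0)
  cell <- disc_mask(S, 128, 128, 64) | nuc
  s2 <- mask_sample(nuc, cell = cell)
  ef <- ellipse_fit(nuc)
  tr <- contour_trace(cell)
  dr <- tr$points[, 1] - ef$centroid[1]
  dc <- tr$points[, 2] - ef$centroid[2]
  uu <- dr * cos(ef$orientation) + dc * sin(ef$orientation)
  vv <- -dr * sin(ef$orientation) + dc * cos(ef$orientation)
  out <- (uu / ef$semimajor_a)^2 + (vv / ef$semiminor_b)^2 > 1
  c_oracle <- max(sqrt(dr^2 + dc^2)[out])
  expected <- (ef$semimajor_a + c_oracle) / (ef$semiminor_b + c_oracle)
  expect_equal(hand_mirror_ratio(s2), expected, tolerance = 1e-12)
  # with a = 2b and c = ~2b the proportion is near 4/3
  expect_lt(abs(hand_mirror_ratio(s2) - 4 / 3), 0.07)
})

test_that("fractal dimension: line ~1, smooth disc in [0.9, 1.2]", {
  line <- matrix(FALSE, 128, 128)
  line[64, 10:118] <- TRUE
  expect_lt(abs(fractal_dimension(line) - 1), 0.15)
  d_disc <- fractal_dimension(disc_mask(128, 64, 64, 50))
  expect_gte(d_disc, 0.9)
  expect_lte(d_disc, 1.2)
})

test_that("contour moments: circle variance ~0, star skew ~0, moment inequality", {
  tr <- contour_trace(disc_mask(128, 64, 64, 40))
  cm <- contour_moments(tr)
  expect_lte(cm[["variance"]], 0.5)

  # symmetric two-radius star: distances alternate, skewness ~ 0; verified
  # against directly enumerated contour distances
  S <- 200
  rows <- matrix(seq_len(S) - 0.5, S, S)
  cols <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
  th <- atan2(cols - 100, rows - 100)
  r <- sqrt((rows - 100)^2 + (cols - 100)^2)
  star <- r <= 60 + 15 * cos(8 * th)
  tr2 <- contour_trace(star)
  cm2 <- contour_moments(tr2)
  expect_lt(abs(cm2[["skewness"]]), 0.1)
  d <- sqrt((tr2$points[, 1] - tr2$centroid[1])^2 +
            (tr2$points[, 2] - tr2$centroid[2])^2)
  n <- length(d); mu <- mean(d)
  m2 <- sum((d - mu)^2) / n; m3 <- sum((d - mu)^3) / n; m4 <- sum((d - mu)^4) / n
  expect_equal(cm2[["variance"]], m2, tolerance = 1e-12)
  expect_equal(cm2[["skewness"]], m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(cm2[["kurtosis"]], m4 / m2^2, tolerance = 1e-12)
  # non-excess kurtosis >= skewness^2 + 1 for any distance sequence
  for (msk in list(star, disc_mask(96, 48, 48, 30),
                   ellipse_mask(96, 48, 48, 36, 14, 0.7))) {
    cmx <- contour_moments(contour_trace(msk))
    expect_gte(cmx[["kurtosis"]], cmx[["skewness"]]^2 + 1 - 1e-9)
  }
})
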