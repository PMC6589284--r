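# Programmatic fixtures: rasterized discs/ellipses and small labelled
# samples used across the suite.

disc_mask <- function(S, ctr_r, ctr_c, r) {
  rows <- matrix(seq_len(S) - 0.5, S, S)
  cols <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
  (rows - ctr_r)^2 + (cols - ctr_c)^2 <= r^2
}

ellipse_mask <- function(S, ctr_r, ctr_c, a, b, phi = 0) {
  rows <- matrix(seq_len(S) - 0.5, S, S)
  cols <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
  u <- (rows - ctr_r) * cos(phi) + (cols - ctr_c) * sin(phi)
  v <- -(rows - ctr_r) * sin(phi) + (cols - ctr_c) * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

flat_image <- function(S, rgb = c(200, 200, 200)) {
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Concentric-disc sample: nucleus radius r_nuc inside cell radius r_cell.
disc_sample <- function(S = 256, r_cell = 80, r_nuc = 40,
                        label = "lymphocyte") {
  cell <- disc_mask(S, S / 2, S / 2, r_cell)
  nuc <- disc_mask(S, S / 2, S / 2, r_nuc)
  img <- flat_image(S, c(230, 230, 240))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[cell] <- c(170, 180, 220)[ch]
    plane[nuc] <- c(100, 70, 150)[ch]
    img[, , ch] <- plane
  }
  labeled_sample(img, cell, nuc, label, source_id = "disc")
}

# Sample with an arbitrary nucleus mask painted over a disc cell.
mask_sample <- function(nucleus, cell = NULL, label = "pre_T") {
  S <- nrow(nucleus)
  if (is.null(cell)) cell <- disc_mask(S, S / 2, S / 2, S * 0.45) | nucleus
  img <- flat_image(S, c(230, 230, 240))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[cell] <- 180
    plane[nucleus] <- 90
    img[, , ch] <- plane
  }
  labeled_sample(img, cell, nucleus, label, source_id = "mask_fixture")
}

# Replace the grayscale nucleus patch content of a disc sample by an
# explicit patch (all three channels set equal), for texture tests.
patch_sample <- function(patch) {
  h <- nrow(patch); w <- ncol(patch)
  S <- max(h, w) + 8
  nuc <- matrix(FALSE, S, S)
  nuc[4 + seq_len(h), 4 + seq_len(w)] <- TRUE
  cell <- disc_mask(S, S / 2, S / 2, S / 2 - 1) | nuc
  img <- flat_image(S, c(240, 240, 240))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[4 + seq_len(h), 4 + seq_len(w)] <- patch
    img[, , ch] <- plane
  }
  labeled_sample(img, cell, nuc, "pre_B", source_id = "patch_fixture")
}

# Tiny dummy sample (8x8) used where only labels/identities matter.
tiny_sample <- function(label, id) {
  m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
  n <- matrix(FALSE, 8, 8); n[4:5, 4:5] <- TRUE
  labeled_sample(flat_image(8), m, n, label, source_id = id)
}

# A 12-sample well-separated training fixture at 64 px, 4 per class.
overfit_fixture <- function() {
  ph <- default_phenotypes("separated")
  unlist(lapply(blast_classes(), function(cl) {
    lapply(1:4, function(i) generate_cell(cl, ph[[cl]], seed = i,
                                          image_size = 64))
  }), recursive = FALSE)
}

sample_labels <- function(samples) vapply(samples, `[[`, "", "label")
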