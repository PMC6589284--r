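test_that("sample validation enforces mask invariants", {
  s <- disc_sample()
  expect_s3_class(s, "labeled_sample")
  # nucleus escaping the cell is rejected
  bad_nuc <- s$nucleus_mask
  bad_nuc[1, 1] <- TRUE
  expect_error(
    labeled_sample(s$image, s$cell_mask, bad_nuc, "lymphocyte"),
    "nucleus not subset of cell"
  )
  expect_error(
    labeled_sample(s$image, s$cell_mask, matrix(FALSE, 256, 256), "lymphocyte"),
    "at least one foreground"
  )
  expect_error(
    labeled_sample(s$image, s$cell_mask[1:100, 1:100], s$nucleus_mask,
                   "lymphocyte"),
    "dimension mismatch"
  )
})

test_that("write/load round-trip is pixel-identical and rescales larger input", {
  dir <- withr::local_tempdir()
  s <- disc_sample()
  p <- write_sample(s, dir)
  s2 <- load_sample(p$image_path, p$cell_mask_path, p$nucleus_mask_path,
                    "lymphocyte")
  expect_identical(dim(s2$image), dim(s$image))
  expect_equal(s2$image, s$image)
  expect_identical(s2$cell_mask, s$cell_mask)
  expect_identical(s2$nucleus_mask, s$nucleus_mask)

  # a 512x512 input comes back as a 256x256 validated sample with binary,
  # nested masks
  big <- disc_sample(S = 512, r_cell = 160, r_nuc = 80)
  pb <- write_sample(big, dir, stem = "big")
  sb <- load_sample(pb$image_path, pb$cell_mask_path, pb$nucleus_mask_path,
                    "pre_T")
  expect_identical(dim(sb$image)[1:2], c(256L, 256L))
  expect_true(all(sb$nucleus_mask <= sb$cell_mask))
  expect_type(sb$cell_mask[1, 1], "logical")
  # areas scale by ~1/4
  expect_lt(abs(sum(sb$cell_mask) / sum(big$cell_mask) - 0.25), 0.01)
})

test_that("manifest round-trip restores the dataset", {
  dir <- withr::local_tempdir()
  samples <- list(disc_sample(S = 64, r_cell = 24, r_nuc = 12),
                  generate_cell("pre_T", default_phenotypes()$pre_T, 3,
                                image_size = 64))
  samples[[1]]$source_id <- "a"; samples[[2]]$source_id <- "b"
  write_dataset(samples, dir)
  back <- read_dataset(file.path(dir, "manifest.csv"))
  expect_length(back, 2)
  expect_equal(sample_labels(back), c("lymphocyte", "pre_T"))
})

test_that("paper-mode splits have 31/45/45 composition, are disjoint and reproducible", {
  counts <- c(lymphocyte = 93, pre_T = 135, pre_B = 135)
  samples <- unlist(lapply(names(counts), function(cl) {
    lapply(seq_len(counts[[cl]]), function(i) tiny_sample(cl, paste0(cl, i)))
  }), recursive = FALSE)
  splits <- make_splits(samples, 10, seed_list = 1:10)
  expect_length(splits, 10)
  for (sp in splits) {
    for (part in list(sp$train, sp$validation, sp$test)) {
      expect_length(part, 121)
      tab <- table(sample_labels(part))
      expect_equal(unname(tab[blast_classes()]), c(31, 45, 45),
                   ignore_attr = TRUE)
    }
    ids <- lapply(list(sp$train, sp$validation, sp$test),
                  function(p) vapply(p, `[[`, "", "source_id"))
    expect_length(unique(unlist(ids)), 363)  # pairwise disjoint
  }
  # same seeds -> identical splits
  splits2 <- make_splits(samples, 10, seed_list = 1:10)
  for (k in 1:10) {
    expect_identical(
      vapply(splits[[k]]$test, `[[`, "", "source_id"),
      vapply(splits2[[k]]$test, `[[`, "", "source_id")
    )
  }
})

test_that("split descriptors record partition source ids and the seed", {
  samples <- unlist(lapply(blast_classes(), function(cl) {
    lapply(1:3, function(i) tiny_sample(cl, paste0(cl, i)))
  }), recursive = FALSE)
  sp <- make_splits(samples, 1, 99, class_counts = c(1, 1, 1))[[1]]
  path <- file.path(withr::local_tempdir(), "split.json")
  write_split_json(sp, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$seed, 99)
  expect_length(back$train, 3)
  expect_length(intersect(back$train, back$test), 0)
})

test_that("insufficient class pools are rejected", {
  samples <- c(
    lapply(1:30, function(i) tiny_sample("lymphocyte", paste0("l", i))),
    lapply(1:135, function(i) tiny_sample("pre_T", paste0("t", i))),
    lapply(1:135, function(i) tiny_sample("pre_B", paste0("b", i)))
  )
  expect_error(make_splits(samples, 1, 1), "insufficient samples")
})
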