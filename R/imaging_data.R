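# Loading, validation, rescaling and splitting of single-cell images.
#
# Conventions used throughout the package: images are numeric arrays
# (rows, cols, 3) with 8-bit channel values in [0, 255], row-major with the
# origin at the top-left; masks are logical matrices aligned to their image,
# TRUE = foreground. Exported pixel coordinates (contours) are 0-based.

TARGET_SIZE <- 256L

#' Construct and validate a labelled single-cell sample
#'
#' A `labeled_sample` bundles one RGB cell image with its whole-cell and
#' nucleus segmentation masks and a class label. The nucleus mask must be a
#' subset of the cell mask and both masks must be non-empty and aligned to
#' the image.
#'
#' @param image numeric array `(H, W, 3)`, channel values in `[0, 255]`.
#' @param cell_mask,nucleus_mask logical (or 0/1) matrices of size `(H, W)`.
#' @param label one of [blast_classes()].
#' @param source_id opaque identifier string.
#' @return an object of class `labeled_sample`.
#' @export
labeled_sample <- function(image, cell_mask, nucleus_mask, label,
                           source_id = "sample") {
  label <- match.arg(label, BLAST_CLASSES)
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an (H, W, 3) array")
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("image channel values must lie in [0, 255]")
  }
  if (!is_binary_mask(cell_mask) || !is_binary_mask(nucleus_mask)) {
    stop("masks must be binary matrices")
  }
  cell_mask <- as_mask(cell_mask)
  nucleus_mask <- as_mask(nucleus_mask)
  if (!identical(dim(cell_mask), dim(image)[1:2]) ||
      !identical(dim(nucleus_mask), dim(image)[1:2])) {
    stop("mask/image dimension mismatch")
  }
  if (!any(cell_mask) || !any(nucleus_mask)) {
    stop("each mask must contain at least one foreground pixel")
  }
  if (any(nucleus_mask & !cell_mask)) {
    stop("nucleus not subset of cell")
  }
  structure(
    list(image = image, cell_mask = cell_mask, nucleus_mask = nucleus_mask,
         label = label, source_id = as.character(source_id)),
    class = "labeled_sample"
  )
}

#' @export
print.labeled_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<labeled_sample '%s'> %dx%d %s | cell %d px, nucleus %d px\n",
    x$source_id, d[1], d[2], x$label, sum(x$cell_mask), sum(x$nucleus_mask)
  ))
  invisible(x)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", path)
  )
  x * 255
}

rescale_image <- function(image, size = TARGET_SIZE) {
  if (all(dim(image)[1:2] == size)) return(image)
  out <- EBImage::resize(image, w = size, h = size, filter = "bilinear")
  clamp(out, 0, 255)
}

rescale_mask <- function(mask, size = TARGET_SIZE) {
  m <- mask * 1.0
  if (!all(dim(m)[1:2] == size)) {
    m <- EBImage::resize(m, w = size, h = size, filter = "none")
  }
  m >= 0.5
}

#' Load a labelled sample from image and mask files
#'
#' Reads an RGB cell image (PNG or TIFF) and its two single-channel masks,
#' rescales everything to 256 x 256 (image: bilinear; masks:
#' nearest-neighbour, then re-binarised at threshold 128) and validates the
#' result.
#'
#' @param image_path path to the RGB cell image.
#' @param cell_mask_path,nucleus_mask_path paths to single-channel masks,
#'   foreground encoded as 255 (any value >= 128 counts as foreground).
#' @param label class label.
#' @param source_id identifier; defaults to the image file name.
#' @return a [labeled_sample()].
#' @export
load_sample <- function(image_path, cell_mask_path, nucleus_mask_path, label,
                        source_id = NULL) {
  img <- read_raster(image_path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  read_mask <- function(p) {
    m <- read_raster(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m >= 128
  }
  cm <- read_mask(cell_mask_path)
  nm <- read_mask(nucleus_mask_path)
  if (!identical(dim(cm), dim(img)[1:2]) || !identical(dim(nm), dim(img)[1:2])) {
    stop("mask/image dimension mismatch")
  }
  labeled_sample(
    image = rescale_image(img),
    cell_mask = rescale_mask(cm),
    nucleus_mask = rescale_mask(nm),
    label = label,
    source_id = if (is.null(source_id)) basename(image_path) else source_id
  )
}

#' Write a labelled sample as PNG image + mask files
#'
#' Files are written in the package's dataset dialect: the image as 8-bit RGB
#' PNG, the masks as single-channel PNG with foreground = 255.
#'
#' @param sample a [labeled_sample()].
#' @param dir output directory (created if missing).
#' @param stem file stem; defaults to the sample's `source_id`.
#' @return invisibly, a named list of the three file paths.
#' @export
write_sample <- function(sample, dir, stem = NULL) {
  stopifnot(inherits(sample, "labeled_sample"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- sample$source_id
  paths <- list(
    image_path = file.path(dir, paste0(stem, ".png")),
    cell_mask_path = file.path(dir, paste0(stem, "_cell.png")),
    nucleus_mask_path = file.path(dir, paste0(stem, "_nucleus.png"))
  )
  png::writePNG(sample$image / 255, paths$image_path)
  png::writePNG(sample$cell_mask * 1.0, paths$cell_mask_path)
  png::writePNG(sample$nucleus_mask * 1.0, paths$nucleus_mask_path)
  invisible(paths)
}

#' Write a dataset manifest CSV
#'
#' @param samples list of [labeled_sample()] objects.
#' @param dir output directory for images, masks and `manifest.csv`.
#' @return invisibly, the manifest data frame (columns `image_path`,
#'   `cell_mask_path`, `nucleus_mask_path`, `label`).
#' @export
write_dataset <- function(samples, dir) {
  rows <- lapply(samples, function(s) {
    p <- write_sample(s, dir)
    data.frame(image_path = p$image_path, cell_mask_path = p$cell_mask_path,
               nucleus_mask_path = p$nucleus_mask_path, label = s$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load every sample listed in a manifest CSV
#'
#' @param manifest_path path to a CSV with columns `image_path`,
#'   `cell_mask_path`, `nucleus_mask_path`, `label` (paths relative to the
#'   manifest's directory or absolute).
#' @return list of [labeled_sample()] objects.
#' @export
read_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  lapply(seq_len(nrow(man)), function(i) {
    load_sample(resolve(man$image_path[i]), resolve(man$cell_mask_path[i]),
                resolve(man$nucleus_mask_path[i]), man$label[i])
  })
}

#' Build stratified train/validation/test splits
#'
#' Reproduces the evaluation protocol: for each seed, samples are drawn
#' without replacement per class, and the draw is dealt into train,
#' validation and test partitions with identical class composition
#' (`class_counts` each). Partitions within a split are disjoint; different
#' splits may reuse samples (when the pool size equals exactly three times
#' the requested counts, each split is a permutation of the whole pool).
#'
#' @param samples list of [labeled_sample()] objects.
#' @param n_splits number of splits to generate.
#' @param seed_list integer vector of length `n_splits`, one RNG seed per
#'   split.
#' @param class_counts named integer vector over [blast_classes()] giving the
#'   per-class count placed in each of the three partitions (paper protocol:
#'   `c(lymphocyte = 31, pre_T = 45, pre_B = 45)`).
#' @return list of `dataset_split` objects, each with elements `train`,
#'   `validation`, `test` (lists of samples) and `seed`.
#' @export
make_splits <- function(samples, n_splits, seed_list,
                        class_counts = c(lymphocyte = 31, pre_T = 45, pre_B = 45)) {
  stopifnot(length(seed_list) == n_splits)
  if (is.null(names(class_counts))) names(class_counts) <- BLAST_CLASSES
  labels <- vapply(samples, `[[`, "", "label")
  by_class <- split(seq_along(samples), factor(labels, levels = BLAST_CLASSES))
  for (cl in names(class_counts)) {
    need <- 3L * class_counts[[cl]]
    if (length(by_class[[cl]]) < need) {
      stop(sprintf("insufficient samples of class %s: need %d, have %d",
                   cl, need, length(by_class[[cl]])))
    }
  }
  lapply(seq_len(n_splits), function(k) {
    idx <- with_seed(seed_list[k], {
      parts <- list(train = integer(), validation = integer(), test = integer())
      for (cl in names(class_counts)) {
        n <- class_counts[[cl]]
        draw <- sample(by_class[[cl]], 3L * n, replace = FALSE)
        parts$train <- c(parts$train, draw[seq_len(n)])
        parts$validation <- c(parts$validation, draw[n + seq_len(n)])
        parts$test <- c(parts$test, draw[2L * n + seq_len(n)])
      }
      parts
    })
    structure(
      list(train = samples[idx$train], validation = samples[idx$validation],
           test = samples[idx$test], seed = seed_list[k]),
      class = "dataset_split"
    )
  })
}

#' Write a split descriptor as JSON
#'
#' Records the `source_id`s of each partition and the split seed; enough to
#' replay the split against the same manifest.
#'
#' @param split a `dataset_split` from [make_splits()].
#' @param path output JSON path.
#' @export
write_split_json <- function(split, path) {
  ids <- lapply(split[c("train", "validation", "test")], function(part) {
    vapply(part, `[[`, "", "source_id")
  })
  jsonlite::write_json(c(ids, list(seed = split$seed)), path, auto_unbox = TRUE)
  invisible(path)
}
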