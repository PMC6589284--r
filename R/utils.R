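#' @keywords internal
"_PACKAGE"

# Class labels, in fixed order. Index 1 is the "normal" class; the cascade and
# all confusion matrices use this ordering.
BLAST_CLASSES <- c("lymphocyte", "pre_T", "pre_B")

#' Class labels recognised by the package
#'
#' @return Character vector `c("lymphocyte", "pre_T", "pre_B")`, in the order
#'   used by confusion matrices and model outputs.
#' @export
blast_classes <- function() BLAST_CLASSES

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a child seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483587L)
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m) {
  storage.mode(m) <- "logical"
  m
}

#' Sample an image with an affine map and bilinear interpolation
#'
#' Output pixel centres are pulled back through the *inverse* transform
#' `coords_in = A %*% coords_out + b` (coordinates are (row, col), 0-based,
#' origin top-left, relative to the image centre). Samples outside the input
#' are clamped to the nearest edge pixel.
#'
#' @param img numeric array `(H, W)` or `(H, W, C)`.
#' @param A 2x2 matrix of the inverse map.
#' @param b length-2 offset of the inverse map (pixels).
#' @param out_dim output `(rows, cols)`; defaults to the input size.
#' @return array of dimension `(out_dim, C)` (channels kept).
#' @keywords internal
affine_sample <- function(img, A, b = c(0, 0), out_dim = NULL) {
  d <- dim(img)
  if (length(d) == 2) {
    img <- array(img, c(d, 1L))
    d <- dim(img)
  }
  H <- d[1]; W <- d[2]; C <- d[3]
  if (is.null(out_dim)) out_dim <- c(H, W)
  oh <- out_dim[1]; ow <- out_dim[2]
  ctr_out <- c((oh - 1) / 2, (ow - 1) / 2)
  ctr_in <- c((H - 1) / 2, (W - 1) / 2)
  r_out <- rep(seq_len(oh) - 1, times = ow) - ctr_out[1]
  c_out <- rep(seq_len(ow) - 1, each = oh) - ctr_out[2]
  r_in <- A[1, 1] * r_out + A[1, 2] * c_out + b[1] + ctr_in[1]
  c_in <- A[2, 1] * r_out + A[2, 2] * c_out + b[2] + ctr_in[2]
  r_in <- clamp(r_in, 0, H - 1)
  c_in <- clamp(c_in, 0, W - 1)
  r0 <- floor(r_in); c0 <- floor(c_in)
  fr <- r_in - r0; fc <- c_in - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  out <- array(0, c(oh, ow, C))
  i00 <- r0 + 1 + H * c0; i01 <- r0 + 1 + H * c1
  i10 <- r1 + 1 + H * c0; i11 <- r1 + 1 + H * c1
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  for (ch in seq_len(C)) {
    plane <- img[, , ch]
    out[, , ch] <- matrix(
      w00 * plane[i00] + w01 * plane[i01] + w10 * plane[i10] + w11 * plane[i11],
      oh, ow
    )
  }
  out
}
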