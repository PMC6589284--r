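# A small convolutional network for 3-class cell-image classification:
# three convolution + ReLU + 2x2 max-pool blocks (32/32/64 filters of size
# 3, zero-padded "same"), flatten, dense ReLU layer of width 64, dropout
# 0.5, and a 3-unit output layer with per-class sigmoid activation trained
# against one-hot targets with binary cross-entropy (a softmax switch is
# available). Convolutions are evaluated as im2col + GEMM; gradients are
# exact backpropagation; optimization is Adam.

#' Network architecture specification
#'
#' Defaults reproduce the reference architecture for 256 x 256 RGB input:
#' spatial sizes 256 -> 128 -> 64 -> 32 through the three pooled blocks and
#' flatten width `64 * 32 * 32 = 65536`. The attached cost-model layers use
#' the single-channel (`n_0 = 1`) counting convention.
#'
#' @param input_size input spatial side length (pixels).
#' @param n_channels input channels consumed by the model (3 for RGB).
#' @param conv_filters filter counts of the convolutional blocks.
#' @param filter_size spatial filter length (3).
#' @param pool_size max-pooling window and stride (2).
#' @param dense_width width of the hidden dense layer (64).
#' @param n_classes output width (3).
#' @param dropout dropout fraction after the hidden dense layer.
#' @param output_activation `"sigmoid"` (as architected) or `"softmax"`.
#' @return a `network_spec` object; `$conv_sizes` holds the conv output
#'   sizes `m_l`, `$flatten_width` the flattened feature count.
#' @export
network_spec <- function(input_size = 256, n_channels = 3,
                         conv_filters = c(32, 32, 64), filter_size = 3,
                         pool_size = 2, dense_width = 64, n_classes = 3,
                         dropout = 0.5,
                         output_activation = c("sigmoid", "softmax")) {
  output_activation <- match.arg(output_activation)
  d <- length(conv_filters)
  conv_sizes <- input_size / pool_size^(seq_len(d) - 1)
  final <- input_size / pool_size^d
  stopifnot(final == round(final), all(conv_sizes == round(conv_sizes)))
  n_prev_tab <- c(1, conv_filters[-d])  # cost-table convention: n_0 = 1
  complexity_layers <- lapply(seq_len(d), function(l) {
    conv_layer_spec(l, n_prev_tab[l], filter_size, conv_filters[l],
                    conv_sizes[l])
  })
  structure(
    list(input_size = as.integer(input_size), n_channels = as.integer(n_channels),
         conv_filters = as.integer(conv_filters),
         filter_size = as.integer(filter_size), pool_size = as.integer(pool_size),
         dense_width = as.integer(dense_width), n_classes = as.integer(n_classes),
         dropout = dropout, output_activation = output_activation,
         conv_sizes = as.integer(conv_sizes),
         flatten_width = as.integer(final^2 * conv_filters[d]),
         complexity_layers = complexity_layers),
    class = "network_spec"
  )
}

#' Geometric augmentation policy
#'
#' Each training image yields `copies_per_image` images: the unchanged
#' original plus randomly transformed copies (horizontal flip with
#' probability 0.5, counterclockwise shear drawn uniformly from
#' `[0, shear_max]` radians, isotropic zoom drawn uniformly from
#' `zoom_range`). The defaults expand a 121-image training set to 2420.
#'
#' @param horizontal_flip enable random horizontal flips.
#' @param shear_max maximum shear angle (radians).
#' @param zoom_range `(low, high)` zoom factors.
#' @param copies_per_image total copies per input, original included.
#' @return an `augmentation_policy` object.
#' @export
augmentation_policy <- function(horizontal_flip = TRUE, shear_max = 0.2,
                                zoom_range = c(0.8, 1.2),
                                copies_per_image = 20) {
  stopifnot(shear_max >= 0, length(zoom_range) == 2,
            zoom_range[1] > 0, zoom_range[2] >= zoom_range[1],
            copies_per_image >= 1)
  structure(
    list(horizontal_flip = horizontal_flip, shear_max = shear_max,
         zoom_range = zoom_range, copies_per_image = as.integer(copies_per_image)),
    class = "augmentation_policy"
  )
}

#' Training configuration
#'
#' Reference settings: batch 121, 50 epochs, learning rate 0.001.
#'
#' @param batch_size minibatch size.
#' @param epochs training epochs; the augmented training set is regenerated
#'   with a fresh derived seed at every epoch.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization, augmentation,
#'   shuffling and dropout.
#' @return a `train_config` object.
#' @export
train_config <- function(batch_size = 121, epochs = 50, learning_rate = 0.001,
                         seed = 1) {
  structure(
    list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Augment a training set
#'
#' @param train_set list of [labeled_sample()] objects.
#' @param policy an [augmentation_policy()].
#' @param seed integer seed; the output is deterministic given
#'   `(train_set, policy, seed)`.
#' @return list with `images` (list of `(H, W, 3)` arrays scaled to
#'   `[0, 1]`) and `labels` (character vector), of length
#'   `copies_per_image * length(train_set)`.
#' @export
augment <- function(train_set, policy, seed) {
  stopifnot(length(train_set) > 0, inherits(policy, "augmentation_policy"))
  with_seed(seed, {
    images <- vector("list", length(train_set) * policy$copies_per_image)
    labels <- character(length(images))
    k <- 0L
    for (s in train_set) {
      x <- s$image / 255
      for (cp in seq_len(policy$copies_per_image)) {
        k <- k + 1L
        labels[k] <- s$label
        if (cp == 1L) {
          images[[k]] <- x
        } else {
          flip <- policy$horizontal_flip && stats::runif(1) < 0.5
          shear <- stats::runif(1, 0, policy$shear_max)
          zoom <- stats::runif(1, policy$zoom_range[1], policy$zoom_range[2])
          M <- diag(2)
          if (flip) M <- M %*% diag(c(1, -1))
          M <- M %*% matrix(c(1, tan(shear), 0, 1), 2, 2)  # ccw shear
          M <- M %*% diag(c(zoom, zoom))
          images[[k]] <- affine_sample(x, solve(M))
        }
      }
    }
    list(images = images, labels = labels)
  })
}

# --- internal network machinery ------------------------------------------

# Patch-index table mapping each (output pixel, kernel offset, channel) to a
# linear index into the zero-padded input volume.
make_conv_index <- function(H, W, C, k) {
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, k * k * C)
  j <- 0L
  for (ch in seq_len(C)) {
    for (dc in seq_len(k) - 1L - pad) {
      for (dr in seq_len(k) - 1L - pad) {
        j <- j + 1L
        idx[, j] <- (r + pad + dr) + Hp * (c + pad + dc - 1L) +
          Hp * Wp * (ch - 1L)
      }
    }
  }
  list(idx = idx, H = H, W = W, C = C, k = k, pad = pad, Hp = Hp, Wp = Wp)
}

# 2x2/stride-2 pooling child indices for an H x W plane (column-major).
make_pool_index <- function(H, W, p = 2L) {
  H2 <- H %/% p; W2 <- W %/% p
  r2 <- rep(seq_len(H2), times = W2)
  c2 <- rep(seq_len(W2), each = H2)
  children <- vapply(seq_len(p * p) - 1L, function(o) {
    dr <- o %% p; dc <- o %/% p
    (p * (r2 - 1L) + dr + 1L) + H * (p * (c2 - 1L) + dc)
  }, integer(H2 * W2))
  if (!is.matrix(children)) children <- matrix(children, nrow = 1L)
  list(children = children, H2 = H2, W2 = W2)
}

pad_volume <- function(x, ci) {
  # x: (H*W) x C matrix -> padded vector of length Hp*Wp*C
  out <- array(0, c(ci$Hp, ci$Wp, ci$C))
  out[ci$pad + seq_len(ci$H), ci$pad + seq_len(ci$W), ] <-
    array(x, c(ci$H, ci$W, ci$C))
  as.vector(out)
}

conv_forward <- function(x, ci, Wm, b) {
  xp <- pad_volume(x, ci)
  col <- matrix(xp[ci$idx], nrow(ci$idx), ncol(ci$idx))
  z <- sweep(col %*% Wm, 2, b, `+`)
  list(col = col, z = z)
}

conv_backward <- function(dz, col, ci, Wm) {
  dW <- crossprod(col, dz)
  db <- colSums(dz)
  dcol <- dz %*% t(Wm)
  dxp <- numeric(ci$Hp * ci$Wp * ci$C)
  for (j in seq_len(ncol(ci$idx))) {
    ii <- ci$idx[, j]
    dxp[ii] <- dxp[ii] + dcol[, j]
  }
  dxa <- array(dxp, c(ci$Hp, ci$Wp, ci$C))
  dx <- dxa[ci$pad + seq_len(ci$H), ci$pad + seq_len(ci$W), , drop = FALSE]
  list(dW = dW, db = db, dx = matrix(dx, ci$H * ci$W, ci$C))
}

pool_forward <- function(a, pi_) {
  # a: (H*W) x F -> pooled (H2*W2) x F with argmax bookkeeping
  n_out <- nrow(pi_$children)
  F <- ncol(a)
  p2 <- ncol(pi_$children)
  # candidate matrix: (n_out * F) rows (output unit), p^2 columns (children)
  cand <- vapply(seq_len(p2),
                 function(o) as.vector(a[pi_$children[, o], , drop = FALSE]),
                 numeric(n_out * F))
  arg <- max.col(cand, ties.method = "first")
  pooled <- matrix(cand[cbind(seq_along(arg), arg)], n_out, F)
  list(out = pooled, arg = arg)
}

pool_backward <- function(dpool, arg, pi_, n_in) {
  n_out <- nrow(dpool)
  F <- ncol(dpool)
  rows_out <- rep(seq_len(n_out), times = F)
  win_row <- pi_$children[cbind(rows_out, arg)]
  dx <- matrix(0, n_in, F)
  dx[cbind(win_row, rep(seq_len(F), each = n_out))] <- as.vector(dpool)
  dx
}

init_weights <- function(spec, seed) {
  with_seed(seed, {
    C_in <- c(spec$n_channels, spec$conv_filters[-length(spec$conv_filters)])
    k2 <- spec$filter_size^2
    conv <- lapply(seq_along(spec$conv_filters), function(l) {
      fan_in <- k2 * C_in[l]
      list(W = matrix(stats::rnorm(fan_in * spec$conv_filters[l], 0,
                                   sqrt(2 / fan_in)),
                      fan_in, spec$conv_filters[l]),
           b = numeric(spec$conv_filters[l]))
    })
    d1 <- list(W = matrix(stats::rnorm(spec$flatten_width * spec$dense_width,
                                       0, sqrt(2 / spec$flatten_width)),
                          spec$flatten_width, spec$dense_width),
               b = numeric(spec$dense_width))
    d2 <- list(W = matrix(stats::rnorm(spec$dense_width * spec$n_classes,
                                       0, sqrt(1 / spec$dense_width)),
                          spec$dense_width, spec$n_classes),
               b = numeric(spec$n_classes))
    list(conv = conv, dense1 = d1, dense2 = d2)
  })
}

make_geometry <- function(spec) {
  sizes <- spec$conv_sizes
  C_in <- c(spec$n_channels, spec$conv_filters[-length(spec$conv_filters)])
  list(
    conv = lapply(seq_along(sizes), function(l) {
      make_conv_index(sizes[l], sizes[l], C_in[l], spec$filter_size)
    }),
    pool = lapply(seq_along(sizes), function(l) {
      make_pool_index(sizes[l], sizes[l], spec$pool_size)
    })
  )
}

# Forward pass for one image (x: (H*W) x C matrix, [0, 1] scale).
net_forward <- function(x, wts, geom, spec, dropout_mask = NULL) {
  cache <- list(conv = vector("list", length(wts$conv)))
  a <- x
  for (l in seq_along(wts$conv)) {
    cf <- conv_forward(a, geom$conv[[l]], wts$conv[[l]]$W, wts$conv[[l]]$b)
    relu <- cf$z > 0
    act <- cf$z * relu
    pf <- pool_forward(act, geom$pool[[l]])
    cache$conv[[l]] <- list(col = cf$col, relu = relu, arg = pf$arg,
                            n_in = nrow(act))
    a <- pf$out
  }
  flat <- as.vector(a)
  z1 <- drop(crossprod(wts$dense1$W, flat)) + wts$dense1$b
  h1 <- pmax(z1, 0)
  h1d <- if (is.null(dropout_mask)) h1 else h1 * dropout_mask
  z2 <- drop(crossprod(wts$dense2$W, h1d)) + wts$dense2$b
  scores <- if (spec$output_activation == "sigmoid") {
    1 / (1 + exp(-z2))
  } else {
    e <- exp(z2 - max(z2)); e / sum(e)
  }
  cache$flat <- flat; cache$z1 <- z1; cache$h1d <- h1d
  cache$scores <- scores
  cache
}

net_loss <- function(scores, y_onehot, activation) {
  eps <- 1e-12
  if (activation == "sigmoid") {
    -sum(y_onehot * log(scores + eps) + (1 - y_onehot) * log(1 - scores + eps))
  } else {
    -sum(y_onehot * log(scores + eps))
  }
}

net_backward <- function(cache, y_onehot, wts, geom, spec, grads) {
  dz2 <- cache$scores - y_onehot  # BCE/sigmoid and CE/softmax share this form
  grads$dense2$W <- grads$dense2$W + outer(cache$h1d, dz2)
  grads$dense2$b <- grads$dense2$b + dz2
  dh1 <- drop(wts$dense2$W %*% dz2)
  dz1 <- dh1 * (cache$z1 > 0)
  grads$dense1$W <- grads$dense1$W + outer(cache$flat, dz1)
  grads$dense1$b <- grads$dense1$b + dz1
  dflat <- drop(wts$dense1$W %*% dz1)
  nl <- length(wts$conv)
  dpool <- matrix(dflat, ncol = spec$conv_filters[nl])
  for (l in rev(seq_len(nl))) {
    cc <- cache$conv[[l]]
    dact <- pool_backward(dpool, cc$arg, geom$pool[[l]], cc$n_in)
    dz <- dact * cc$relu
    cb <- conv_backward(dz, cc$col, geom$conv[[l]], wts$conv[[l]]$W)
    grads$conv[[l]]$W <- grads$conv[[l]]$W + cb$dW
    grads$conv[[l]]$b <- grads$conv[[l]]$b + cb$db
    if (l > 1) dpool <- cb$dx
  }
  grads
}

zero_like <- function(wts) {
  rapply(wts, function(x) x * 0, how = "replace")
}

adam_update <- function(wts, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- Map(walk, w, g, m, v)
      return(list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  res <- walk(wts, grads, state$m, state$v)
  list(wts = res$w, state = list(m = res$m, v = res$v))
}

sample_to_x <- function(image01, spec) {
  matrix(image01, spec$input_size^2, spec$n_channels)
}

label_onehot <- function(label, spec) {
  y <- numeric(spec$n_classes)
  y[match(label, BLAST_CLASSES)] <- 1
  y
}

# Mean loss and error rate over a list of images (forward only, no dropout).
net_evaluate <- function(images01, labels, wts, geom, spec) {
  n <- length(images01)
  loss <- 0; correct <- 0
  for (i in seq_len(n)) {
    cache <- net_forward(sample_to_x(images01[[i]], spec), wts, geom, spec)
    y <- label_onehot(labels[i], spec)
    loss <- loss + net_loss(cache$scores, y, spec$output_activation)
    pred <- which.max(cache$scores)  # ties: lowest class index
    correct <- correct + (BLAST_CLASSES[pred] == labels[i])
  }
  list(loss = loss / n, error = 1 - correct / n)
}

#' Train the convolutional network
#'
#' Each epoch regenerates the augmented training set from the original
#' training images with a fresh seed derived from `cfg$seed` and the epoch
#' number, shuffles it, performs Adam updates on minibatches of
#' `cfg$batch_size`, and records the validation error and cross-entropy
#' loss. Fully deterministic given the inputs and `cfg$seed`.
#'
#' @param train_set,validation_set lists of [labeled_sample()] objects whose
#'   images match `spec$input_size`.
#' @param spec a [network_spec()].
#' @param policy an [augmentation_policy()].
#' @param cfg a [train_config()].
#' @return a `trained_convnet`: `weights`, `spec`, and `training_log` (data
#'   frame with one row per epoch: `epoch`, `train_loss`, `val_loss`,
#'   `val_error`).
#' @export
train_convnet <- function(train_set, validation_set, spec, policy, cfg) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "train_config"))
  if (!all(vapply(train_set, function(s) all(dim(s$image)[1:2] == spec$input_size),
                  TRUE))) {
    stop("training images do not match spec$input_size")
  }
  geom <- make_geometry(spec)
  wts <- init_weights(spec, cfg$seed)
  state <- list(m = zero_like(wts), v = zero_like(wts))
  val_images <- lapply(validation_set, function(s) s$image / 255)
  val_labels <- vapply(validation_set, `[[`, "", "label")
  log_rows <- vector("list", cfg$epochs)
  t_step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    aug <- augment(train_set, policy, derive_seed(cfg$seed, epoch))
    n <- length(aug$images)
    ord <- with_seed(derive_seed(cfg$seed, 100000L + epoch), sample.int(n))
    epoch_loss <- 0
    b0 <- 1L
    while (b0 <= n) {
      batch <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      grads <- zero_like(wts)
      for (i in batch) {
        dm <- if (spec$dropout > 0) {
          with_seed(derive_seed(cfg$seed, 200000L + t_step * 1000L + i),
                    (stats::runif(spec$dense_width) >= spec$dropout) /
                      (1 - spec$dropout))
        } else NULL
        cache <- net_forward(sample_to_x(aug$images[[i]], spec), wts, geom,
                             spec, dropout_mask = dm)
        y <- label_onehot(aug$labels[i], spec)
        epoch_loss <- epoch_loss +
          net_loss(cache$scores, y, spec$output_activation)
        grads <- net_backward(cache, y, wts, geom, spec, grads)
      }
      grads <- rapply(grads, function(g) g / length(batch), how = "replace")
      t_step <- t_step + 1L
      upd <- adam_update(wts, grads, state, cfg$learning_rate, t_step)
      wts <- upd$wts; state <- upd$state
      b0 <- b0 + cfg$batch_size
    }
    ev <- net_evaluate(val_images, val_labels, wts, geom, spec)
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                    val_loss = ev$loss, val_error = ev$error)
  }
  structure(
    list(weights = wts, spec = spec, training_log = do.call(rbind, log_rows)),
    class = "trained_convnet"
  )
}

#' Predict class labels and per-class scores
#'
#' @param model a `trained_convnet`.
#' @param samples list of [labeled_sample()] objects, or list of `(H, W, 3)`
#'   arrays on either the `[0, 1]` or `[0, 255]` scale.
#' @return list with `labels` (character) and `scores` (N x 3 matrix);
#'   predicted label is the argmax, ties broken by lowest class index.
#' @export
predict_convnet <- function(model, samples) {
  stopifnot(inherits(model, "trained_convnet"))
  spec <- model$spec
  geom <- make_geometry(spec)
  images <- lapply(samples, function(s) {
    x <- if (inherits(s, "labeled_sample")) s$image else s
    if (max(x) > 1) x <- x / 255
    if (!all(dim(x)[1:2] == spec$input_size)) stop("image dimension mismatch")
    x
  })
  scores <- matrix(0, length(images), spec$n_classes,
                   dimnames = list(NULL, BLAST_CLASSES))
  for (i in seq_along(images)) {
    scores[i, ] <- net_forward(sample_to_x(images[[i]], spec), model$weights,
                               geom, spec)$scores
  }
  list(labels = BLAST_CLASSES[max.col(scores, ties.method = "first")],
       scores = scores)
}
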