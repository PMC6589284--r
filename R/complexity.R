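# Convolutional operation-count model: per-layer cost
# n_{l-1} * s_l^2 * n_l * m_l^2 and its sum over the convolutional
# sublayers. The counts use the cost-table channel convention n_0 = 1 (each
# colour channel counted separately), which deliberately differs from the
# trained model's 3-channel input; both conventions are kept as given.

#' Specification of one convolutional sublayer for the cost model
#'
#' @param index_l layer index `l`.
#' @param n_prev input feature-map count `n_{l-1}`.
#' @param filter_size_s spatial filter length `s_l`.
#' @param n_filters output map count `n_l`.
#' @param out_size_m output spatial size `m_l`.
#' @return a `conv_layer_spec` object.
#' @export
conv_layer_spec <- function(index_l, n_prev, filter_size_s, n_filters,
                            out_size_m) {
  stopifnot(index_l >= 1, n_prev >= 1, filter_size_s >= 1, n_filters >= 1,
            out_size_m >= 1)
  structure(
    list(index_l = index_l, n_prev = n_prev, filter_size_s = filter_size_s,
         n_filters = n_filters, out_size_m = out_size_m),
    class = "conv_layer_spec"
  )
}

#' Convolutional operations of one sublayer
#'
#' @param layer a [conv_layer_spec()].
#' @return `n_prev * s^2 * n_filters * m^2`, exact.
#' @export
conv_ops_per_layer <- function(layer) {
  stopifnot(inherits(layer, "conv_layer_spec"))
  layer$n_prev * layer$filter_size_s^2 * layer$n_filters * layer$out_size_m^2
}

#' Total convolutional operations of a network
#'
#' @param spec a [network_spec()] (its cost-model layers use the `n_0 = 1`
#'   convention) or a list of [conv_layer_spec()] objects.
#' @return sum of [conv_ops_per_layer()] over all convolutional sublayers.
#' @export
total_conv_ops <- function(spec) {
  layers <- if (inherits(spec, "network_spec")) spec$complexity_layers else spec
  if (length(layers) == 0) return(0)
  sum(vapply(layers, conv_ops_per_layer, 0))
}

#' Per-layer and total convolutional operation counts as a table
#'
#' @param spec a [network_spec()] or list of [conv_layer_spec()] objects.
#' @return data frame with columns `l`, `n_prev`, `s`, `n`, `m`, `ops` and
#'   an attribute `total`; one row per convolutional sublayer.
#' @export
complexity_report <- function(spec) {
  layers <- if (inherits(spec, "network_spec")) spec$complexity_layers else spec
  df <- do.call(rbind, lapply(layers, function(x) {
    data.frame(l = x$index_l, n_prev = x$n_prev, s = x$filter_size_s,
               n = x$n_filters, m = x$out_size_m,
               ops = conv_ops_per_layer(x))
  }))
  attr(df, "total") <- total_conv_ops(layers)
  df
}

#' Forward and training operation counts
#'
#' A training pass counts the forward convolutions plus the backward
#' gradient convolutions (with respect to inputs and to weights), three
#' times the forward-only cost of a test-time pass.
#'
#' @param spec a [network_spec()] or list of [conv_layer_spec()] objects.
#' @return list with `forward` and `training` operation counts.
#' @export
conv_op_costs <- function(spec) {
  fwd <- total_conv_ops(spec)
  list(forward = fwd, training = 3 * fwd)
}
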