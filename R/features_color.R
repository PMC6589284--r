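# Colour descriptors (features 35-46): mean RGB and mean HSV over the
# nucleus and over the cytoplasm (cell minus nucleus). RGB means stay on the
# [0, 255] channel scale; H, S and V are on [0, 1] (hexcone conversion, hue
# of achromatic pixels defined as 0).

region_color_means <- function(image, mask, prefix) {
  idx <- which(mask)
  rgb <- rbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  out <- c(rowMeans(rgb), rowMeans(hsv))
  names(out) <- paste0(prefix, c("_mean_R", "_mean_G", "_mean_B",
                                 "_mean_H", "_mean_S", "_mean_V"))
  out
}

#' Colour features (35-46)
#'
#' @param sample a [labeled_sample()].
#' @return named numeric vector of length 12: nucleus mean R, G, B, H, S, V
#'   followed by the cytoplasm means in the same order.
#' @export
color_features <- function(sample) {
  cyto <- sample$cell_mask & !sample$nucleus_mask
  if (!any(cyto)) stop("degenerate sample: empty cytoplasm")
  c(region_color_means(sample$image, sample$nucleus_mask, "nuc"),
    region_color_means(sample$image, cyto, "cyto"))
}
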