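# Voxel-wise model-attention maps. Each routine returns a nonnegative
# activation map at input resolution together with an adjustable display
# threshold: values below threshold_fraction * max(map) are hidden, the
# originals kept so the threshold can be changed dynamically.

new_activation_map <- function(values, source, layer = NULL,
                               threshold_fraction = 0.2) {
  values[values < 0] <- 0
  m <- structure(list(values = values, source = source, layer = layer,
                      threshold_fraction = threshold_fraction),
                 class = "voxann_activation_map")
  auto_threshold(m, threshold_fraction)
}

#' @export
print.voxann_activation_map <- function(x, ...) {
  cat(sprintf("%s map %s: max %.4g, threshold %.0f%% (%d of %d hidden)\n",
              x$source, paste(dim(x$values), collapse = "x"),
              max(x$values), 100 * x$threshold_fraction,
              sum(x$hidden), length(x$values)))
  invisible(x)
}

#' Hide low activations below a fraction of the map maximum
#'
#' @param map a `voxann_activation_map`.
#' @param fraction threshold fraction in [0, 1); values strictly below
#'   `fraction * max` are hidden. Re-thresholding always works from the
#'   stored original values.
#' @return the map with an updated `hidden` mask and `visible` values
#'   (hidden entries set to `NA`).
#' @export
auto_threshold <- function(map, fraction = 0.2) {
  if (fraction < 0 || fraction >= 1)
    va_stop("validation", "threshold fraction must be in [0, 1)")
  cut <- fraction * max(map$values)
  hidden <- map$values < cut
  vis <- map$values
  vis[hidden] <- NA
  map$threshold_fraction <- fraction
  map$hidden <- hidden
  map$visible <- vis
  map
}

#' Saliency map
#'
#' Absolute gradient of the class score with respect to the input image,
#' reduced over input channels by the maximum.
#'
#' @param net a `voxann_toynet` classification model.
#' @param section input 2-D matrix or H x W x C array.
#' @param class_index 1-based class index of the score to explain.
#' @param threshold_fraction display threshold (default 0.2).
#' @return a `voxann_activation_map`.
#' @export
saliency <- function(net, section, class_index, threshold_fraction = 0.2) {
  gr <- toynet_gradients(net, section, class_index)
  g <- abs(gr$input)
  if (length(dim(g)) == 3) g <- apply(g, c(1, 2), max)
  new_activation_map(g, "saliency", NULL, threshold_fraction)
}

spatial_layers <- function(net) {
  which(vapply(net$layers, function(l) l$type == "conv2d", logical(1)))
}

#' Gradient-weighted class activation map (Grad-CAM)
#'
#' At a spatial layer with feature maps A^k, the channel weights are the
#' spatial means of the class-score gradient, and the map is
#' ReLU(sum_k alpha_k A^k), bilinearly upsampled to input resolution.
#'
#' @inheritParams saliency
#' @param layer 1-based index of a spatial (conv) layer.
#' @export
grad_cam <- function(net, section, class_index, layer = NULL,
                     threshold_fraction = 0.2) {
  sp <- spatial_layers(net)
  if (!length(sp))
    va_stop("unsupported_layer", "model has no spatial layers")
  layer <- layer %||% max(sp)
  if (!layer %in% sp)
    va_stop("unsupported_layer", "layer ", layer,
            " has no spatial feature maps")
  gr <- toynet_gradients(net, section, class_index)
  A <- gr$forward$activations[[layer]]
  G <- gr$layers[[layer]]
  alpha <- apply(G, 3, mean)
  map <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) map <- map + alpha[k] * A[, , k]
  map <- pmax(map, 0)
  d_in <- dim(section)[1:2]
  map <- bilinear_resize(map, d_in[1], d_in[2])
  new_activation_map(map, "grad_cam", layer, threshold_fraction)
}

# A CAM architecture is: spatial layers, then global average pooling, then a
# single linear dense classification layer.
check_cam_architecture <- function(net) {
  types <- vapply(net$layers, `[[`, "", "type")
  n <- length(types)
  ok <- n >= 3 && types[n] == "dense" && types[n - 1] == "gap" &&
    identical(net$layers[[n]]$activation %||% "linear", "linear") &&
    all(types[seq_len(n - 2)] == "conv2d")
  if (!ok)
    va_stop("architecture", "CAM requires a GAP + single linear dense head ",
            "over spatial layers")
  n - 2L   # index of the final spatial layer
}

#' Class activation map (CAM)
#'
#' Requires the CAM-specific architecture (global average pooling followed by
#' one linear classification layer); other models raise an architecture
#' error. The map is the classification weights' combination of the final
#' spatial feature maps, negative values clipped for display.
#'
#' @inheritParams saliency
#' @export
cam <- function(net, section, class_index, threshold_fraction = 0.2) {
  last_spatial <- check_cam_architecture(net)
  fw <- toynet_forward(net, section)
  A <- fw$activations[[last_spatial]]
  Wc <- net$layers[[length(net$layers)]]$W[, class_index]
  map <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(Wc)) map <- map + Wc[k] * A[, , k]
  map <- pmax(map, 0)
  d_in <- dim(section)[1:2]
  map <- bilinear_resize(map, d_in[1], d_in[2])
  new_activation_map(map, "cam", last_spatial, threshold_fraction)
}

#' Saliency activation map (SAM)
#'
#' Combines where the model looks (saliency) with what activates (Grad-CAM):
#' the elementwise product of the min-max-normalised saliency and Grad-CAM
#' maps, renormalised to [0, 1]. The combination rule is pluggable via
#' `combine`.
#'
#' @inheritParams grad_cam
#' @param combine `function(saliency_values, gradcam_values) -> values`;
#'   the default is the normalised product.
#' @export
sam <- function(net, section, class_index, layer = NULL,
                threshold_fraction = 0.2, combine = NULL) {
  s <- saliency(net, section, class_index, threshold_fraction)
  g <- grad_cam(net, section, class_index, layer, threshold_fraction)
  norm01 <- function(v) {
    mx <- max(v)
    if (mx == 0) v else v / mx
  }
  vals <- if (is.null(combine)) {
    prod <- norm01(s$values) * norm01(g$values)
    if (max(prod) == 0) {
      va_warn("numeric", "degenerate component map; SAM is identically zero")
      prod
    } else prod / max(prod)
  } else combine(s$values, g$values)
  new_activation_map(vals, "sam", g$layer, threshold_fraction)
}

#' Export an activation map as a NIfTI slice overlay
#'
#' Writes the raw map values aligned to the input slice geometry.
#'
#' @param map a `voxann_activation_map`.
#' @param path output `.nii.gz` path.
#' @param affine optional 4x4 affine of the source slice.
#' @export
write_activation_map <- function(map, path, affine = diag(4)) {
  arr <- array(map$values, c(dim(map$values), 1L))
  img <- make_nifti(arr, affine)
  RNifti::writeNifti(img, path)
  invisible(path)
}
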