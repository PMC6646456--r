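# A small sequential network engine over plain R arrays. It exists so that
# metadata-driven inference and gradient-based visualisation are fully
# exercisable (and unit-testable) with deterministic toy models: dense,
# 2-D same-padding convolution, global average pooling and flatten layers
# with linear / relu / sigmoid activations, exact forward passes, and
# reverse-mode gradients with respect to the input and any layer's output.
# Weights round-trip through HDF5 so model bundles behave like real ones.

act_fun <- function(name) {
  switch(name,
         linear = list(f = identity, df = function(z) z * 0 + 1),
         relu = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
         sigmoid = list(f = stats::plogis,
                        df = function(z) stats::plogis(z) *
                          (1 - stats::plogis(z))),
         va_stop("validation", "unknown activation: ", name))
}

#' Build a toy sequential network
#'
#' @param layers list of layer descriptors, each a list with `type`
#'   (`"dense"`, `"conv2d"`, `"gap"`, `"flatten"`) and, for parameterised
#'   layers, `W`, `b` and `activation`. Dense weights are (in x out);
#'   conv2d kernels are (kh x kw x in_channels x out_channels), stride 1,
#'   same zero padding.
#' @param input_shape expected input shape (H, W, C) or a vector length for
#'   dense-only networks.
#' @return an object of class `voxann_toynet`.
#' @export
toynet <- function(layers, input_shape) {
  structure(list(layers = layers, input_shape = as.integer(input_shape)),
            class = "voxann_toynet")
}

#' @export
print.voxann_toynet <- function(x, ...) {
  cat("toy network:", length(x$layers), "layer(s), input",
      paste(x$input_shape, collapse = "x"), "\n")
  invisible(x)
}

conv2d_forward <- function(x, W, b) {
  # x: H x W x Cin; W: kh x kw x Cin x Cout; stride 1, same zero padding
  d <- dim(x); kh <- dim(W)[1]; kw <- dim(W)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  xp <- array(0, c(d[1] + kh - 1, d[2] + kw - 1, cin))
  xp[ph + seq_len(d[1]), pw + seq_len(d[2]), ] <- x
  out <- array(0, c(d[1], d[2], cout))
  for (o in seq_len(cout)) {
    acc <- matrix(b[o], d[1], d[2])
    for (i in seq_len(kh)) for (j in seq_len(kw)) for (ci in seq_len(cin)) {
      acc <- acc + W[i, j, ci, o] *
        xp[(i - 1) + seq_len(d[1]), (j - 1) + seq_len(d[2]), ci]
    }
    out[, , o] <- acc
  }
  out
}

conv2d_backward_input <- function(g, W, xdim) {
  # g: H x W x Cout gradient at (pre-activation) output; returns dL/dx
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  gp <- array(0, c(xdim[1] + kh - 1, xdim[2] + kw - 1, cin))
  for (o in seq_len(cout)) {
    for (i in seq_len(kh)) for (j in seq_len(kw)) for (ci in seq_len(cin)) {
      gp[(i - 1) + seq_len(xdim[1]), (j - 1) + seq_len(xdim[2]), ci] <-
        gp[(i - 1) + seq_len(xdim[1]), (j - 1) + seq_len(xdim[2]), ci] +
        W[i, j, ci, o] * g[, , o]
    }
  }
  gp[ph + seq_len(xdim[1]), pw + seq_len(xdim[2]), , drop = FALSE]
}

# Forward pass keeping every layer's pre-activation and activation.
toynet_forward <- function(net, x) {
  if (length(dim(x) %||% integer(0)) == 2) x <- array(x, c(dim(x), 1L))
  acts <- list(); pres <- list()
  cur <- x
  for (li in seq_along(net$layers)) {
    lay <- net$layers[[li]]
    if (lay$type == "conv2d") {
      z <- conv2d_forward(cur, lay$W, lay$b)
      a <- act_fun(lay$activation %||% "linear")$f(z)
    } else if (lay$type == "dense") {
      z <- as.numeric(matrix(as.numeric(cur), 1) %*% lay$W) + lay$b
      a <- act_fun(lay$activation %||% "linear")$f(z)
    } else if (lay$type == "gap") {
      d <- dim(cur)
      z <- apply(cur, 3, mean)
      a <- z
    } else if (lay$type == "flatten") {
      z <- as.numeric(cur)
      a <- z
    } else va_stop("validation", "unknown layer type: ", lay$type)
    pres[[li]] <- z
    acts[[li]] <- a
    cur <- a
  }
  list(output = cur, activations = acts, preacts = pres, input = x)
}

#' Run a toy network
#'
#' @param net a `voxann_toynet`.
#' @param x input array (H x W x C, or a matrix treated as one channel).
#' @return the network output (class-score vector, or array for
#'   fully-convolutional networks).
#' @export
toynet_predict <- function(net, x) toynet_forward(net, x)$output

# Reverse-mode gradient of output[class_index] w.r.t. the input and w.r.t.
# every layer's (post-activation) output.
toynet_gradients <- function(net, x, class_index) {
  fw <- toynet_forward(net, x)
  nl <- length(net$layers)
  out <- fw$output
  g <- if (is.null(dim(out))) {
    v <- numeric(length(out)); v[class_index] <- 1; v
  } else {
    a <- array(0, dim(out)); a[, , class_index] <- 1; a
  }
  layer_grads <- vector("list", nl)
  for (li in nl:1) {
    lay <- net$layers[[li]]
    layer_grads[[li]] <- g   # gradient w.r.t. this layer's output
    below <- if (li == 1) fw$input else fw$activations[[li - 1]]
    if (lay$type == "dense") {
      dz <- g * act_fun(lay$activation %||% "linear")$df(fw$preacts[[li]])
      g_below <- as.numeric(lay$W %*% dz)
      g <- if (is.null(dim(below))) g_below else array(g_below, dim(below))
    } else if (lay$type == "conv2d") {
      dz <- g * act_fun(lay$activation %||% "linear")$df(fw$preacts[[li]])
      g <- conv2d_backward_input(dz, lay$W, dim(below))
    } else if (lay$type == "gap") {
      d <- dim(below)
      g <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
    } else if (lay$type == "flatten") {
      g <- array(g, dim(below))
    }
  }
  list(input = g, layers = layer_grads, forward = fw)
}

# ---- HDF5 weight bundles -----------------------------------------------------

#' Save / load toy-network weights as HDF5
#'
#' Layer parameters and architecture live in one HDF5 file, the on-disk form
#' model bundles are distributed in.
#'
#' @param net a `voxann_toynet`.
#' @param path HDF5 file path.
#' @export
toynet_save_h5 <- function(net, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(length(net$layers), path, "n_layers")
  rhdf5::h5write(net$input_shape, path, "input_shape")
  for (li in seq_along(net$layers)) {
    lay <- net$layers[[li]]
    grp <- sprintf("layer_%02d", li)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(lay$type, path, file.path(grp, "type"))
    if (!is.null(lay$W)) rhdf5::h5write(lay$W, path, file.path(grp, "W"))
    if (!is.null(lay$b)) rhdf5::h5write(lay$b, path, file.path(grp, "b"))
    if (!is.null(lay$activation))
      rhdf5::h5write(lay$activation, path, file.path(grp, "activation"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname toynet_save_h5
#' @export
toynet_load_h5 <- function(path) {
  if (!file.exists(path)) va_stop("io", "no such weights file: ", path)
  n <- as.integer(rhdf5::h5read(path, "n_layers"))
  input_shape <- as.integer(rhdf5::h5read(path, "input_shape"))
  layers <- vector("list", n)
  for (li in seq_len(n)) {
    grp <- sprintf("layer_%02d", li)
    names_in <- rhdf5::h5ls(path)
    have <- names_in$name[names_in$group == paste0("/", grp)]
    lay <- list(type = as.character(rhdf5::h5read(path,
                                                  file.path(grp, "type"))))
    if ("W" %in% have) lay$W <- rhdf5::h5read(path, file.path(grp, "W"))
    if ("b" %in% have) lay$b <- as.numeric(rhdf5::h5read(path,
                                                         file.path(grp, "b")))
    if ("activation" %in% have)
      lay$activation <- as.character(rhdf5::h5read(path,
                                                   file.path(grp,
                                                             "activation")))
    layers[[li]] <- lay
  }
  rhdf5::h5closeAll()
  toynet(layers, input_shape)
}
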