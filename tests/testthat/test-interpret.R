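test_that("saliency of a scaled-sum model is its coefficient everywhere", {
  # y = 3 * sum(x): flatten + dense with all-3 weights
  net <- toynet(list(list(type = "flatten"),
                     list(type = "dense", W = matrix(3, 16, 1), b = 0,
                          activation = "linear")),
                input_shape = c(4, 4, 1))
  s <- saliency(net, matrix(rnorm(16), 4, 4), 1)
  expect_true(all(abs(s$values - 3) < 1e-12))
  expect_true(all(s$values >= 0))
})

test_that("gradient maps match central finite differences on a small network", {
  net <- cam_toynet()
  x <- matrix(rnorm(36), 6, 6)
  g <- voxann:::toynet_gradients(net, x, 2)$input[, , 1]
  fd <- matrix(0, 6, 6); eps <- 1e-5
  for (i in 1:6) for (j in 1:6) {
    xp <- x; xm <- x
    xp[i, j] <- x[i, j] + eps; xm[i, j] <- x[i, j] - eps
    fd[i, j] <- (toynet_predict(net, xp)[2] -
                   toynet_predict(net, xm)[2]) / (2 * eps)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-3)
})

test_that("grad-cam weighs feature maps by mean gradient and clips at zero", {
  # single feature map, GAP + identity dense: alpha = 1/(H*W), map ~ relu(A)
  A_w <- array(0, c(3, 3, 1, 1)); A_w[2, 2, 1, 1] <- 1   # identity conv
  net <- toynet(list(
    list(type = "conv2d", W = A_w, b = 0, activation = "linear"),
    list(type = "gap"),
    list(type = "dense", W = matrix(1, 1, 1), b = 0, activation = "linear")
  ), input_shape = c(4, 4, 1))
  x <- matrix(c(2, -3, 1, 0, 4, -1, 5, -2, 3, 1, -4, 2, 0, 1, 2, -5), 4, 4)
  gc <- grad_cam(net, x, 1)
  expect_equal(gc$values, pmax(x, 0) / 16, tolerance = 1e-12)
  # negative combinations are exactly zero after the relu
  expect_true(all(gc$values[x < 0] == 0))
  # a dense-only model has no spatial layer to visualise
  dense_net <- toynet(list(list(type = "flatten"),
                           list(type = "dense", W = matrix(1, 16, 2),
                                b = c(0, 0), activation = "linear")),
                      input_shape = c(4, 4, 1))
  expect_error(grad_cam(dense_net, x, 1),
               class = "voxann_unsupported_layer_error")
})

test_that("cam equals final-layer grad-cam on a GAP-linear model", {
  net <- cam_toynet()
  x <- matrix(rnorm(36), 6, 6)
  for (cls in 1:3) {
    cm <- cam(net, x, cls)
    gc <- grad_cam(net, x, cls)
    if (max(cm$values) == 0) {
      expect_equal(max(gc$values), 0)
      next
    }
    # identical up to the positive 1/(H*W) factor of the gradient weights
    expect_lt(max(abs(cm$values / max(cm$values) -
                        gc$values / max(gc$values))), 1e-5)
    expect_equal(cm$values, gc$values * 36, tolerance = 1e-9)
  }
})

test_that("cam refuses architectures without a GAP-linear head", {
  x <- matrix(rnorm(36), 6, 6)
  flat_net <- toynet(list(
    list(type = "conv2d", W = array(1, c(3, 3, 1, 1)), b = 0,
         activation = "relu"),
    list(type = "flatten"),
    list(type = "dense", W = matrix(rnorm(72), 36, 2), b = c(0, 0),
         activation = "linear")
  ), input_shape = c(6, 6, 1))
  expect_error(cam(flat_net, x, 1), class = "voxann_architecture_error")
  sigmoid_head <- toynet(list(
    list(type = "conv2d", W = array(1, c(3, 3, 1, 1)), b = 0,
         activation = "relu"),
    list(type = "gap"),
    list(type = "dense", W = matrix(1, 1, 2), b = c(0, 0),
         activation = "sigmoid")
  ), input_shape = c(6, 6, 1))
  expect_error(cam(sigmoid_head, x, 1), class = "voxann_architecture_error")
})

test_that("sam is the normalised product of its components", {
  net <- cam_toynet()
  x <- matrix(rnorm(36), 6, 6)
  s <- saliency(net, x, 2); g <- grad_cam(net, x, 2)
  sm <- sam(net, x, 2)
  expect_true(all(sm$values >= 0))
  expect_lte(max(sm$values), 1)
  # support is contained in the intersection of the component supports
  expect_true(all(sm$values[s$values == 0 | g$values == 0] == 0))
  # identical components give the normalised square
  sq <- sam(net, x, 2, combine = function(a, b) {
    n <- function(v) if (max(v) > 0) v / max(v) else v
    n(a) * n(a)
  })
  expect_equal(sq$values, (s$values / max(s$values))^2, tolerance = 1e-12)
})

test_that("auto-thresholding hides exactly the sub-threshold values, reversibly", {
  m <- voxann:::new_activation_map(matrix(c(0, 0.1, 0.5, 1), 2, 2),
                                   "saliency")
  at <- auto_threshold(m, 0.2)
  expect_identical(as.vector(at$hidden), c(TRUE, TRUE, FALSE, FALSE))
  # fraction 0 hides nothing
  expect_false(any(auto_threshold(m, 0)$hidden))
  # re-thresholding works from stored originals
  at6 <- auto_threshold(at, 0.6)
  expect_identical(as.vector(at6$hidden), c(TRUE, TRUE, TRUE, FALSE))
  back <- auto_threshold(at6, 0.2)
  expect_identical(back$hidden, at$hidden)
  # idempotence at a fixed fraction
  expect_identical(auto_threshold(at, 0.2)$hidden, at$hidden)
  expect_error(auto_threshold(m, 1), class = "voxann_validation_error")
})

test_that("bilinear upsampling keeps the argmax within one coarse cell", {
  set.seed(71)
  for (rep in 1:20) {
    coarse <- matrix(runif(16), 4, 4)
    # a strict maximum: with near-ties the interpolated peak may sit at a
    # different near-maximal corner, which is not what this checks
    peak <- sample(16, 1)
    coarse[peak] <- max(coarse) + 0.5
    fine <- voxann:::bilinear_resize(coarse, 16, 16)
    cmax <- which(coarse == max(coarse), arr.ind = TRUE)[1, ]
    fmax <- which(fine == max(fine), arr.ind = TRUE)[1, ]
    # fine cell centre mapped back to coarse coordinates
    back <- (fmax - 0.5) * 4 / 16 + 0.5
    expect_lte(max(abs(back - cmax)), 1)
  }
})

test_that("activation maps export as NIfTI aligned to the slice", {
  dir <- withr::local_tempdir()
  net <- cam_toynet()
  s <- saliency(net, matrix(rnorm(36), 6, 6), 1)
  f <- file.path(dir, "sal.nii.gz")
  write_activation_map(s, f)
  v <- RNifti::readNifti(f)
  expect_equal(dim(v)[1:2], c(6, 6))
  expect_equal(matrix(as.numeric(v), 6, 6), s$values, tolerance = 1e-6)
})
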