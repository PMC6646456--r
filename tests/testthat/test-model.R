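test_that("model import validates, versions and activates", {
  dir <- withr::local_tempdir()
  w <- file.path(dir, "kidney_seg.h5")
  toynet_save_h5(threshold_net(), w)
  p <- make_project(rois = "kidney", shape = c(32, 32, 8))
  reg <- model_registry()
  spec <- model_spec("kidney_seg", w, input = list(mode = "2d"),
                     normalization = list(method = "minmax"),
                     output = list(task = "segmentation",
                                   mapping = list("1" = "kidney")))
  v1 <- import_model(reg, spec, p)
  v2 <- import_model(reg, spec, p)
  expect_equal(c(v1$version, v2$version), c(1L, 2L))
  expect_equal(reg$active[["kidney_seg"]], 2L)
  expect_equal(get_model(reg, "kidney_seg")$version, 2L)
  # mapping to an undefined ROI fails
  bad <- spec; bad$output$mapping <- list("1" = "liver")
  expect_error(import_model(reg, bad, p), class = "voxann_validation_error")
  # metadata plane shape must match the model input
  bad2 <- spec; bad2$input$plane_shape <- c(16L, 16L)
  expect_error(import_model(reg, bad2, p), class = "voxann_shape_error")
  # missing weights
  bad3 <- spec; bad3$weights_ref <- file.path(dir, "nope.h5")
  expect_error(import_model(reg, bad3, p), class = "voxann_io_error")
})

test_that("model discovery imports new bundles, skips malformed, and is idempotent", {
  dir <- withr::local_tempdir()
  w <- file.path(dir, "kidney_seg.h5")
  toynet_save_h5(threshold_net(), w)
  spec <- model_spec("kidney_seg", w, input = list(mode = "2d"),
                     normalization = list(method = "minmax"),
                     output = list(task = "segmentation",
                                   mapping = list("1" = "kidney")))
  write_model_metadata(spec, file.path(dir, "kidney_seg.model.yaml"))
  writeLines("not: [valid", file.path(dir, "broken.model.yaml"))
  reg <- model_registry()
  r1 <- discover_models(reg, dir)
  expect_length(r1$imported, 1)
  expect_equal(r1$skipped, "broken.model.yaml")
  # unchanged rescan: nothing imported
  r2 <- discover_models(reg, dir)
  expect_length(r2$imported, 0)
  # pushed v3 bundle becomes active
  spec$version <- 3L
  write_model_metadata(spec, file.path(dir, "kidney_seg.model.yaml"))
  discover_models(reg, dir)
  expect_equal(length(reg$entries[["kidney_seg"]]), 2L)
  expect_equal(reg$active[["kidney_seg"]], 3L)
  expect_equal(get_model(reg, "kidney_seg")$version, 3L)
})

test_that("normalization follows its definitions and flags degenerate input", {
  x <- matrix(c(90, 100, 110, 100), 2, 2)
  spec_z <- model_spec("m", "w", input = list(mode = "2d"),
                       normalization = list(method = "zscore"),
                       output = list(task = "segmentation",
                                     mapping = list("1" = "r")))
  z <- preprocess(x, spec_z)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(stats::sd(as.numeric(z)) - 1), 1e-6)
  spec_w <- spec_z; spec_w$normalization <- list(method = "fixed_window",
                                                 window = c(-100, 300))
  expect_equal(preprocess(matrix(500, 1, 1), spec_w)[1, 1], 1)
  expect_equal(preprocess(matrix(-200, 1, 1), spec_w)[1, 1], 0)
  expect_equal(preprocess(matrix(100, 1, 1), spec_w)[1, 1], 0.5)
  spec_m <- spec_z; spec_m$normalization <- list(method = "minmax")
  expect_warning(got <- preprocess(matrix(7, 3, 3), spec_m),
                 class = "voxann_numeric_warning")
  expect_true(all(got == 0))
})

test_that("spatial input ops compose like the brute-force index permutation", {
  x <- matrix(1:6, 2, 3)
  spec <- model_spec("m", "w",
                     input = list(mode = "2d",
                                  affine_ops = list("rot90", "flip_x")),
                     normalization = list(method = "none"),
                     output = list(task = "segmentation",
                                   mapping = list("1" = "r")))
  got <- preprocess(x, spec)
  oracle <- t(x)[ncol(x):1, ]          # rot90 counter-clockwise
  oracle <- oracle[nrow(oracle):1, ]   # then flip rows
  expect_equal(got, oracle)
  # flips and rotations permute, never lose, pixels
  set.seed(61)
  idx <- matrix(sample(100), 10, 10)
  for (ops in list(list("flip_x"), list("flip_y"),
                   list(list("rot90", k = 1)), list(list("rot90", k = 3)),
                   list("flip_x", list("rot90", k = 2), "flip_y"))) {
    sp <- spec; sp$input$affine_ops <- ops
    out <- preprocess(idx, sp)
    expect_setequal(as.integer(out), 1:100)
  }
})

test_that("threshold-network inference equals direct thresholding of the normalized volume", {
  dir <- withr::local_tempdir()
  w <- file.path(dir, "thr.h5")
  toynet_save_h5(threshold_net(), w)
  ph <- generate_phantom(phantom_config(seed = 7))
  p <- make_project(rois = "lesion", image = ph$image)
  spec <- model_spec("thr", w, input = list(mode = "2d", axis = "axial"),
                     normalization = list(method = "minmax"),
                     output = list(task = "segmentation",
                                   mapping = list("1" = "lesion")))
  lv <- infer(p, "s1", spec)
  oracle <- array(FALSE, dim(ph$image))
  for (z in 1:32) {
    s <- ph$image[, , z]
    oracle[, , z] <- (s - min(s)) / (max(s) - min(s)) > 0.5
  }
  expect_identical(lv$labels == 1, oracle)
  # drafted slices carry auto provenance
  z_hit <- which(apply(oracle, 3, any))[1] - 1
  expect_equal(slice_provenance(lv, z_hit, 1), "auto")
  # determinism: identical spec + volume -> identical draft
  p2 <- make_project(rois = "lesion", image = ph$image)
  lv2 <- infer(p2, "s1", spec)
  expect_identical(lv2$labels, lv$labels)
  # locked target ROI refuses drafting
  set_roi_locked(p, "lesion", TRUE)
  expect_error(infer(p, "s1", spec), class = "voxann_locked_roi_error")
})

test_that("patch blend weights are a partition of unity for varied layouts", {
  for (case in list(list(v = c(20, 17, 9), p = c(8, 8, 4)),
                    list(v = c(16, 16, 16), p = c(16, 16, 16)),
                    list(v = c(13, 7, 5), p = c(4, 4, 2)),
                    list(v = c(9, 9, 3), p = c(8, 8, 8)))) {
    bw <- blend_weights(case$v, case$p)
    tot <- array(0, bw$shape)
    pp <- bw$patch
    for (i in seq_len(nrow(bw$starts))) {
      s <- bw$starts[i, ]
      tot[s[1]:(s[1] + pp[1] - 1), s[2]:(s[2] + pp[2] - 1),
          s[3]:(s[3] + pp[3] - 1)] <-
        tot[s[1]:(s[1] + pp[1] - 1), s[2]:(s[2] + pp[2] - 1),
            s[3]:(s[3] + pp[3] - 1)] + bw$weights[[i]]
    }
    expect_lt(max(abs(tot - 1)), 1e-12)
  }
})

test_that("patch-wise inference of a translation-invariant model is uniform", {
  dir <- withr::local_tempdir()
  w <- file.path(dir, "dummy.h5"); file.create(w)
  register_model_loader("const3d_test", function(wr) function(x) {
    d <- dim(x)
    sc <- array(0, c(d, 2)); sc[, , , 1] <- 0.3; sc[, , , 2] <- 0.7
    sc
  })
  p <- make_project(rois = "lesion", image = array(5, c(12, 12, 8)))
  spec <- model_spec("c3", w,
                     input = list(mode = "3d_patch", patch_shape = c(6, 6, 4)),
                     normalization = list(method = "none"),
                     output = list(task = "segmentation",
                                   mapping = list("1" = "lesion")),
                     loader = "const3d_test")
  lv <- infer(p, "s1", spec)
  expect_true(all(lv$labels == 1))
})

test_that("classification inference writes the mapped text value", {
  dir <- withr::local_tempdir()
  w <- file.path(dir, "clf.h5"); file.create(w)
  register_model_loader("argmax_clf_test", function(wr) function(x) {
    # scores favour class 2 whenever the slice mean is positive
    m <- mean(x)
    c(1 - stats::plogis(m), stats::plogis(m))
  })
  p <- make_project(rois = "kidney", image = array(2, c(8, 8, 4)))
  define_text_field(p, "contrast_phase",
                    c("non-contrast", "arterial", "venous", "delayed"))
  spec <- model_spec("phase_clf", w, input = list(mode = "2d", axis = "axial"),
                     normalization = list(method = "none"),
                     output = list(task = "classification",
                                   mapping = list(
                                     "0" = c("contrast_phase", "non-contrast"),
                                     "1" = c("contrast_phase", "venous"))),
                     loader = "argmax_clf_test")
  got <- infer(p, "s1", spec)
  expect_equal(unname(got), c("contrast_phase", "venous"))
  expect_equal(p$series[["s1"]]$text_values$contrast_phase, "venous")
})

test_that("a linear end-to-end model matches its closed form through the harness", {
  # one 1x1 linear conv: score_2 = a*x + b, applied after fixed-window
  # normalization; infer must label exactly {x : a*norm(x)+b > score_1}
  dir <- withr::local_tempdir()
  w <- file.path(dir, "lin.h5")
  a <- 2; b <- -0.6
  net <- toynet(list(list(type = "conv2d",
                          W = array(c(0, a), c(1, 1, 1, 2)),
                          b = c(0.0, b), activation = "linear")),
                input_shape = c(16, 16, 1))
  toynet_save_h5(net, w)
  img <- array(runif(16 * 16 * 4, -50, 150), c(16, 16, 4))
  p <- make_project(rois = "r", image = img)
  spec <- model_spec("lin", w, input = list(mode = "2d"),
                     normalization = list(method = "fixed_window",
                                          window = c(0, 100)),
                     output = list(task = "segmentation",
                                   mapping = list("1" = "r")))
  lv <- infer(p, "s1", spec)
  xn <- pmin(pmax(img / 100, 0), 1)
  expect_identical(lv$labels == 1, a * xn + b > 0)
})
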