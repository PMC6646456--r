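# bit plane helper used across edit tests
bit_test_arr <- function(x, mv) (x %/% mv) %% 2 == 1

test_that("painting honours footprint, threshold and slice extent", {
  img <- array(0, c(10, 10, 10))
  img[6, 6, 6] <- 5; img[7, 6, 6] <- 50; img[8, 6, 6] <- 500
  p <- make_project(image = img)
  # radius-0 brush labels exactly one voxel
  apply_edit(p, "s1", edit_request("kidney", "paint", slice = 5,
                                   center = c(5, 5)))
  lv <- get_label_volume(p, "s1")
  expect_equal(sum(lv$labels), 1)
  expect_equal(lv$labels[6, 6, 6], 1)
  # threshold keeps only in-range voxels of the footprint
  fp <- cbind(x = c(5, 6, 7), y = c(5, 5, 5))
  apply_edit(p, "s1", edit_request("tumor", "paint", slice = 5,
                                   footprint = fp, threshold = c(10, 100)))
  lv <- get_label_volume(p, "s1")
  expect_equal(which(bit_test_arr(lv$labels, 2)), which(img == 50))
  # slice extent clamps at the volume boundary
  p2 <- make_project()
  apply_edit(p2, "s1", edit_request("kidney", "paint", slice = 0,
                                    center = c(4, 4), slice_extent = 1))
  lv2 <- get_label_volume(p2, "s1")
  zs <- unique(which(lv2$labels == 1, arr.ind = TRUE)[, 3])
  expect_equal(sort(zs), c(1, 2))  # 0-based slices 0 and 1
})

test_that("erasing clears only the target ROI's bit", {
  p <- make_project()
  apply_edit(p, "s1", edit_request("kidney", "paint", slice = 4,
                                   center = c(5, 5)))
  apply_edit(p, "s1", edit_request("tumor", "paint", slice = 4,
                                   center = c(5, 5)))
  expect_equal(get_label_volume(p, "s1")$labels[6, 6, 5], 3)
  apply_edit(p, "s1", edit_request("tumor", "erase", slice = 4,
                                   center = c(5, 5)))
  expect_equal(get_label_volume(p, "s1")$labels[6, 6, 5], 1)
})

test_that("threshold subset and locality hold over randomized edits", {
  set.seed(7)
  for (rep in 1:20) {
    img <- array(runif(8^3, 0, 100), c(8, 8, 8))
    p <- make_project(rois = "r", shape = c(8, 8, 8), image = img)
    lo <- runif(1, 10, 40); hi <- lo + runif(1, 10, 40)
    z <- sample(0:7, 1); k <- sample(0:2, 1)
    ctr <- sample(0:7, 2, replace = TRUE); rad <- sample(0:3, 1)
    before <- get_label_volume(p, "s1")$labels
    req <- edit_request("r", "paint", slice = z, center = ctr, radius = rad,
                        slice_extent = k, threshold = c(lo, hi))
    apply_edit(p, "s1", req)
    after <- get_label_volume(p, "s1")$labels
    newly <- which(after == 1 & before == 0)
    # subset: every newly labelled voxel is in the threshold window
    expect_true(all(img[newly] >= lo & img[newly] <= hi))
    # locality: nothing outside footprint x slice-extent changed
    allowed <- array(FALSE, dim(img))
    for (zz in max(0, z - k):min(7, z + k))
      for (i in seq_len(nrow(req$footprint))) {
        x <- req$footprint[i, 1]; y <- req$footprint[i, 2]
        if (x >= 0 && x < 8 && y >= 0 && y < 8)
          allowed[x + 1, y + 1, zz + 1] <- TRUE
      }
    expect_true(all(after[!allowed] == before[!allowed]))
  }
})

test_that("flood fill matches the connected-component oracle", {
  img <- array(0, c(5, 5, 1))
  img[2:4, 2:4, 1] <- 100
  p <- make_project(rois = "r", image = img)
  flood_fill(p, "s1", "r", seed = c(2, 2, 0), threshold = c(50, 150))
  expect_equal(sum(get_label_volume(p, "s1")$labels), 9)
  # seed on background: no-op notice
  p2 <- make_project(rois = "r", image = img)
  expect_message(flood_fill(p2, "s1", "r", seed = c(0, 0, 0),
                            threshold = c(50, 150)), "seed outside")
  expect_equal(sum(get_label_volume(p2, "s1")$labels), 0)
})

test_that("flood fill connectivity: diagonal chains need 8-connectivity", {
  img <- array(0, c(6, 6, 1))
  for (i in 1:5) img[i, i, 1] <- 100
  p4 <- make_project(rois = "r", image = img)
  flood_fill(p4, "s1", "r", seed = c(0, 0, 0), threshold = c(50, 150),
             connectivity = 4)
  expect_equal(sum(get_label_volume(p4, "s1")$labels), 1)
  p8 <- make_project(rois = "r", image = img)
  flood_fill(p8, "s1", "r", seed = c(0, 0, 0), threshold = c(50, 150),
             connectivity = 8)
  expect_equal(sum(get_label_volume(p8, "s1")$labels), 5)
})

test_that("flood fill agrees with EBImage connected components on random slices", {
  set.seed(11)
  for (rep in 1:10) {
    m <- matrix(runif(144) < 0.45, 12, 12)
    img <- array(0, c(12, 12, 1)); img[, , 1][m] <- 100
    seeds <- which(m, arr.ind = TRUE)
    if (nrow(seeds) == 0) next
    sd_ <- seeds[sample(nrow(seeds), 1), ]
    p <- make_project(rois = "r", image = img)
    flood_fill(p, "s1", "r", seed = c(sd_[1] - 1, sd_[2] - 1, 0),
               threshold = c(50, 150), connectivity = 4)
    got <- get_label_volume(p, "s1")$labels[, , 1] == 1
    lab <- EBImage::bwlabel(m * 1)
    expect_identical(got, lab == lab[sd_[1], sd_[2]])
  }
})

test_that("morphology follows the cross element and EBImage oracle", {
  p <- make_project(rois = "r")
  apply_edit(p, "s1", edit_request("r", "paint", slice = 5, center = c(5, 5)))
  morph(p, "s1", "r", "dilate", scope = "slice", slice = 5)
  m <- get_label_volume(p, "s1")$labels[, , 6] == 1
  expect_equal(sum(m), 5)  # 3x3 cross
  morph(p, "s1", "r", "erode", scope = "slice", slice = 5)
  m <- get_label_volume(p, "s1")$labels[, , 6] == 1
  expect_equal(which(m, arr.ind = TRUE), cbind(row = 6L, col = 6L))
  morph(p, "s1", "r", "erode", scope = "slice", slice = 5)
  expect_equal(sum(get_label_volume(p, "s1")$labels), 0)
  # random masks vs EBImage diamond brush
  set.seed(3)
  brush <- EBImage::makeBrush(3, "diamond")
  for (rep in 1:10) {
    m <- matrix(runif(100) < 0.4, 10, 10)
    img <- array(0, c(10, 10, 1))
    p <- make_project(rois = "r", image = img)
    lv <- get_label_volume(p, "s1")
    lv$labels[, , 1][m] <- 1
    voxann:::set_label_volume(p, "s1", lv)
    morph(p, "s1", "r", "dilate", scope = "slice", slice = 0)
    got <- get_label_volume(p, "s1")$labels[, , 1] == 1
    expect_identical(got, EBImage::dilate(m * 1, brush) == 1)
  }
})

test_that("opening is contained in the mask which is contained in closing", {
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(runif(196) < 0.5, 14, 14)
    img <- array(0, c(14, 14, 1))
    open_p <- make_project(rois = "r", image = img)
    lv <- get_label_volume(open_p, "s1"); lv$labels[, , 1][m] <- 1
    voxann:::set_label_volume(open_p, "s1", lv)
    morph(open_p, "s1", "r", "erode", scope = "slice", slice = 0)
    morph(open_p, "s1", "r", "dilate", scope = "slice", slice = 0)
    opening <- get_label_volume(open_p, "s1")$labels[, , 1] == 1
    close_p <- make_project(rois = "r", image = img)
    lv <- get_label_volume(close_p, "s1"); lv$labels[, , 1][m] <- 1
    voxann:::set_label_volume(close_p, "s1", lv)
    morph(close_p, "s1", "r", "dilate", scope = "slice", slice = 0)
    morph(close_p, "s1", "r", "erode", scope = "slice", slice = 0)
    closing <- get_label_volume(close_p, "s1")$labels[, , 1] == 1
    expect_true(all(!opening | m))   # opening(X) subset of X
    expect_true(all(!m | closing))   # X subset of closing(X)
  }
})

test_that("exclusive-mode dilation refuses to grow over other ROIs", {
  p <- make_project(exclusive = TRUE)
  apply_edit(p, "s1", edit_request("kidney", "paint", slice = 5,
                                   center = c(4, 5)))
  apply_edit(p, "s1", edit_request("tumor", "paint", slice = 5,
                                   center = c(5, 5)))
  morph(p, "s1", "tumor", "dilate", scope = "slice", slice = 5)
  lv <- get_label_volume(p, "s1")
  expect_equal(lv$labels[5, 6, 6], 1)   # kidney voxel not overwritten
  expect_true(all(voxann:::bit_popcount(lv$labels) <= 1))
})

test_that("point annotations enforce kind, bounds and uniqueness", {
  p <- project_create()
  define_roi(p, "L3_vertebra", kind = "point")
  define_roi(p, "kidney", kind = "area")
  add_series(p, "s1", image = array(0, c(24, 24, 12)))
  add_point(p, "s1", "L3_vertebra", c(10, 20, 5))
  lv <- get_label_volume(p, "s1")
  expect_equal(nrow(lv$points), 1)
  expect_equal(unlist(lv$points[1, c("x", "y", "z")]),
               c(x = 10, y = 20, z = 5))
  expect_error(add_point(p, "s1", "L3_vertebra", c(10, 20, 5)),
               class = "voxann_validation_error")
  expect_error(add_point(p, "s1", "kidney", c(1, 1, 1)),
               class = "voxann_wrong_tool_error")
  expect_error(apply_edit(p, "s1", edit_request("L3_vertebra", "paint",
                                                slice = 1, center = c(1, 1))),
               class = "voxann_wrong_tool_error")
  expect_error(remove_point(p, "s1", "L3_vertebra", c(0, 0, 0)),
               class = "voxann_lookup_error")
  remove_point(p, "s1", "L3_vertebra", c(10, 20, 5))
  expect_equal(nrow(get_label_volume(p, "s1")$points), 0)
})

test_that("undo and redo restore annotation state bit-exactly", {
  p <- make_project()
  snap0 <- voxann:::labels_snapshot(get_label_volume(p, "s1"))
  apply_edit(p, "s1", edit_request("kidney", "paint", slice = 3,
                                   center = c(4, 4), radius = 2))
  snap1 <- voxann:::labels_snapshot(get_label_volume(p, "s1"))
  apply_edit(p, "s1", edit_request("tumor", "paint", slice = 5,
                                   center = c(6, 6), radius = 1))
  undo(p, "s1"); undo(p, "s1")
  expect_identical(voxann:::labels_snapshot(get_label_volume(p, "s1")), snap0)
  redo(p, "s1")
  expect_identical(voxann:::labels_snapshot(get_label_volume(p, "s1")), snap1)
  # replay oracle: two edits, two undos, one redo = state after first edit
  expect_message(redo(p, "s1"), NA)
  undo(p, "s1"); undo(p, "s1")
  expect_message(undo(p, "s1"), "nothing to undo")
})

test_that("random edit sequences in exclusive mode never multi-label a voxel", {
  set.seed(21)
  img <- array(runif(6^3, 0, 100), c(6, 6, 6))
  p <- make_project(rois = c("a", "b", "c"), image = img, exclusive = TRUE)
  for (step in 1:40) {
    roi <- sample(c("a", "b", "c"), 1)
    op <- sample(c("paint", "erase", "fill", "morph"), 1)
    z <- sample(0:5, 1)
    if (op %in% c("paint", "erase")) {
      apply_edit(p, "s1", edit_request(roi, op, slice = z,
                                       center = sample(0:5, 2, TRUE),
                                       radius = sample(0:2, 1)))
    } else if (op == "fill") {
      suppressMessages(flood_fill(p, "s1", roi,
                                  seed = c(sample(0:5, 2, TRUE), z),
                                  threshold = c(0, runif(1, 20, 90))))
    } else {
      morph(p, "s1", roi, sample(c("dilate", "erode"), 1),
            scope = "slice", slice = z)
    }
    expect_true(all(voxann:::bit_popcount(get_label_volume(p,
                                                           "s1")$labels) <= 1))
  }
})
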