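# Annotation by iterative deep learning (AID) harness. The loop mirrors the
# methodology: annotate a small batch from scratch, train a model on the
# corrected data, let it draft the next batch, correct the drafts, retrain.
# Human correction effort is proxied at desk scale by the symmetric-
# difference voxel count between draft and truth; correction itself is
# perfect (corrected = truth), modelling the reviewed-and-approved end state.

#' Correct a draft annotation against ground truth
#'
#' @param draft,truth `voxann_labels` objects (or logical arrays) of equal
#'   shape; comparison is on one ROI's bit plane for label volumes.
#' @param mask_value the ROI bit to compare when label volumes are given.
#' @return list with `corrected` (= truth) and `edit_cost`, the number of
#'   voxels in the symmetric difference.
#' @export
simulate_correction <- function(draft, truth, mask_value = 1) {
  dm <- if (inherits(draft, "voxann_labels"))
    roi_mask(draft, mask_value) else draft
  tm <- if (inherits(truth, "voxann_labels"))
    roi_mask(truth, mask_value) else truth
  if (!identical(dim(dm), dim(tm)))
    va_stop("shape", "draft and truth shapes differ")
  list(corrected = tm, edit_cost = sum(xor(dm, tm)))
}

# ---- default trainer: per-voxel logistic model on local intensity features --

aid_features <- function(img) {
  # raw intensity plus its in-slice 3x3 box mean (cheap local context)
  d <- dim(img)
  sm <- img
  for (z in seq_len(d[3])) {
    m <- img[, , z]
    acc <- m; cnt <- matrix(1, d[1], d[2])
    for (dx in c(-1L, 0L, 1L)) for (dy in c(-1L, 0L, 1L)) {
      if (dx == 0 && dy == 0) next
      sh <- matrix(0, d[1], d[2])
      xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy
      okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
      sh[okx, oky] <- m[xs[okx], ys[oky]]
      acc <- acc + sh
      cnt[okx, oky] <- cnt[okx, oky] + 1
    }
    sm[, , z] <- acc / cnt
  }
  cbind(intensity = as.numeric(img), local_mean = as.numeric(sm))
}

#' Default AID trainer: per-voxel logistic regression
#'
#' Fits `glm(fg ~ intensity + local_mean, binomial)` on a voxel subsample of
#' the corrected volumes and returns a predictor honouring the model-plugin
#' contract (H x W x 1 section in, H x W x 2 class scores out), wrapped in a
#' segmentation [model_spec()].
#'
#' @param training list of `list(image, truth)` pairs.
#' @param roi_name ROI the drafts should label.
#' @param sample_per_volume voxel subsample size per training volume.
#' @return a `voxann_model_spec` whose loader closure holds the fitted model.
#' @export
logistic_trainer <- function(training, roi_name = "lesion",
                             sample_per_volume = 3000L) {
  feats <- list(); labs <- list()
  for (tr in training) {
    X <- aid_features(tr$image)
    y <- as.numeric(tr$truth)
    n <- length(y)
    idx <- sample.int(n, min(sample_per_volume, n))
    feats[[length(feats) + 1L]] <- X[idx, , drop = FALSE]
    labs[[length(labs) + 1L]] <- y[idx]
  }
  X <- do.call(rbind, feats); y <- unlist(labs)
  df <- data.frame(y = y, intensity = X[, 1], local_mean = X[, 2])
  fit <- suppressWarnings(stats::glm(y ~ intensity + local_mean,
                                     family = stats::binomial(), data = df))
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  loader_name <- paste0("aid_logistic_",
                        digest::digest(cf, algo = "crc32"))
  register_model_loader(loader_name, function(weights_ref) {
    function(x) {
      m <- if (length(dim(x)) == 3) x[, , 1] else x
      vol <- array(m, c(dim(m), 1L))
      X <- aid_features(vol)
      p <- stats::plogis(cf[1] + cf[2] * X[, 1] + cf[3] * X[, 2])
      sc <- array(0, c(dim(m), 2L))
      sc[, , 1] <- 1 - p
      sc[, , 2] <- p
      sc
    }
  })
  model_spec(name = "aid_draft", weights_ref = "",
             input = list(mode = "2d", axis = "axial"),
             normalization = list(method = "none"),
             output = list(task = "segmentation",
                           mapping = list("1" = roi_name), rule = "argmax"),
             loader = loader_name)
}

# import_model / infer demand an existing weights file; AID specs carry their
# fitted coefficients in the loader closure, so weights_ref is a placeholder
# written once per session.
aid_placeholder_weights <- function() {
  f <- file.path(tempdir(), "aid_placeholder.h5")
  if (!file.exists(f)) file.create(f)
  f
}

#' Run the AID loop on a synthetic phantom suite
#'
#' Iteration 0 annotates the first batch from scratch (its edit cost is the
#' full de-novo truth size). Each later iteration trains on all corrected
#' volumes so far, drafts the next batch through the model harness, corrects
#' the drafts against truth, and logs the mean draft Dice and mean edit cost.
#'
#' @param configs list of [phantom_config()]s (the dataset).
#' @param trainer `function(training, roi_name) -> voxann_model_spec`;
#'   default [logistic_trainer()].
#' @param iterations number of AID iterations (>= 2), including iteration 0.
#' @param batch_per_iteration phantoms annotated per iteration.
#' @param seed seed for all loop-level randomness (subsampling in the
#'   trainer included).
#' @param roi_name ROI drafted by the models.
#' @return a `voxann_aid_report`: data frame with one row per iteration
#'   (iteration, training_set_size, mean_draft_dice, mean_edit_cost).
#' @export
run_aid <- function(configs, trainer = logistic_trainer, iterations = 4L,
                    batch_per_iteration = 5L, seed = 1L,
                    roi_name = "lesion") {
  if (iterations < 2) va_stop("validation", "AID needs at least 2 iterations")
  set.seed(seed)
  phantoms <- lapply(configs, generate_phantom)
  n <- length(phantoms)
  rows <- list()
  corrected <- list()
  cursor <- 0L
  for (it in seq_len(iterations) - 1L) {
    take <- seq_len(min(batch_per_iteration, n - cursor)) + cursor
    if (!length(take)) break
    batch <- phantoms[take]
    if (it == 0L) {
      # de-novo annotation: empty drafts corrected to truth
      costs <- vapply(batch, function(ph) sum(ph$truth), 0)
      dices <- rep(0, length(batch))
    } else {
      spec <- trainer(corrected, roi_name)
      spec$weights_ref <- aid_placeholder_weights()
      costs <- numeric(length(batch)); dices <- numeric(length(batch))
      for (bi in seq_along(batch)) {
        ph <- batch[[bi]]
        p <- project_create()
        define_roi(p, roi_name, color = c(255, 0, 0))
        add_series(p, "s", image = ph$image)
        lv <- infer(p, "s", spec)
        mv <- p$rois[[roi_name]]$mask_value
        draft <- roi_mask(lv, mv)
        corr <- simulate_correction(draft, ph$truth)
        costs[bi] <- corr$edit_cost
        dices[bi] <- dice_jaccard(draft, ph$truth)["dice"]
      }
    }
    corrected <- c(corrected,
                   lapply(batch, function(ph)
                     list(image = ph$image, truth = ph$truth)))
    rows[[length(rows) + 1L]] <- data.frame(
      iteration = it, training_set_size = length(corrected),
      mean_draft_dice = mean(dices), mean_edit_cost = mean(costs))
    cursor <- cursor + length(take)
  }
  report <- do.call(rbind, rows)
  class(report) <- c("voxann_aid_report", class(report))
  report
}

#' @export
print.voxann_aid_report <- function(x, ...) {
  cat("AID run:", nrow(x), "iterations\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
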