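# Metadata-driven model harness. A model bundle is an HDF5 weights file plus
# a YAML metadata sidecar describing how to feed the model (slice axis or
# patch shape, spatial transforms, normalization) and how to map its output
# back to annotations (class -> ROI for segmentation, class -> text value for
# classification). Execution is abstracted behind a predict function built by
# a named loader, so any backend honouring the array-in/scores-out contract
# can stand behind a spec.

.loaders <- new.env(parent = emptyenv())

#' Register a model loader hook
#'
#' A loader turns a weights file into a predict function
#' `function(input_array) -> scores`. The built-in `"toynet"` loader reads
#' the package's HDF5 toy-network bundles; custom loaders let other backends
#' plug in.
#'
#' @param name loader identifier referenced by model metadata.
#' @param fn `function(weights_path) -> function(x) scores`.
#' @export
register_model_loader <- function(name, fn) {
  assign(name, fn, envir = .loaders)
  invisible(name)
}

get_model_loader <- function(name) {
  if (!exists(name, envir = .loaders))
    va_stop("lookup", "unknown model loader: '", name, "'")
  get(name, envir = .loaders)
}

#' Describe a model as a metadata spec
#'
#' @param name model name (versions share a name).
#' @param weights_ref path to the HDF5 weights bundle.
#' @param input list: `mode` ("2d" or "3d_patch"); for 2d `axis` ("axial",
#'   "coronal", "sagittal") and optional `plane_shape`; for 3d_patch
#'   `patch_shape`; optional `affine_ops`, an ordered list of `"flip_x"`,
#'   `"flip_y"`, `"rot90"` (with `k`), `list("scale_to_shape", shape)`;
#'   `channels` (default 1).
#' @param normalization list: `method` one of "none", "minmax", "zscore",
#'   "fixed_window" (with `window = c(lo, hi)`).
#' @param output list: `task` ("segmentation" or "classification");
#'   `mapping`, named list class-index -> ROI name (segmentation) or
#'   class-index -> c(field, value) (classification); `rule` ("argmax" or
#'   "threshold" with `threshold`).
#' @param loader loader hook name (default "toynet").
#' @param version positive integer, assigned by the registry on import.
#' @return a `voxann_model_spec`.
#' @export
model_spec <- function(name, weights_ref, input, normalization = list(method = "none"),
                       output, loader = "toynet", version = 1L) {
  input$mode <- input$mode %||% "2d"
  if (!input$mode %in% c("2d", "3d_patch"))
    va_stop("validation", "input mode must be 2d or 3d_patch")
  if (input$mode == "2d") input$axis <- input$axis %||% "axial"
  if (input$mode == "3d_patch" && is.null(input$patch_shape))
    va_stop("validation", "3d_patch mode needs patch_shape")
  if (!normalization$method %in% c("none", "minmax", "zscore",
                                   "fixed_window"))
    va_stop("validation", "unknown normalization method")
  if (!output$task %in% c("segmentation", "classification"))
    va_stop("validation", "output task must be segmentation or classification")
  output$rule <- output$rule %||% "argmax"
  structure(list(name = name, version = as.integer(version),
                 weights_ref = weights_ref, loader = loader, input = input,
                 normalization = normalization, output = output),
            class = "voxann_model_spec")
}

#' @export
print.voxann_model_spec <- function(x, ...) {
  cat(sprintf("model '%s' v%d [%s, %s]: %s\n", x$name, x$version,
              x$input$mode, x$normalization$method, x$output$task))
  invisible(x)
}

# ---- registry ----------------------------------------------------------------

#' Create a model registry
#'
#' Tracks every imported version of every model; the newest import of a name
#' becomes active. History is never deleted.
#'
#' @return a `voxann_model_registry` (environment semantics).
#' @export
model_registry <- function() {
  r <- new.env(parent = emptyenv())
  r$entries <- list()   # name -> list of specs (by version)
  r$active <- list()    # name -> version
  class(r) <- "voxann_model_registry"
  r
}

#' Import a model into a registry
#'
#' Validates the bundle (weights present; for segmentation, mapped ROIs
#' defined and unlocked in the project; metadata plane shape consistent with
#' the loaded model) and registers it. Re-importing a name auto-increments
#' the version and activates it.
#'
#' @param registry a [model_registry()].
#' @param spec a [model_spec()].
#' @param project optional project whose schema the output mapping must
#'   reference.
#' @return the registered spec (with its assigned version), invisibly.
#' @export
import_model <- function(registry, spec, project = NULL) {
  if (!file.exists(spec$weights_ref))
    va_stop("io", "weights file missing: ", spec$weights_ref)
  if (!is.null(project) && spec$output$task == "segmentation") {
    for (nm in unlist(spec$output$mapping)) {
      if (!nm %in% names(project$rois))
        va_stop("validation", "model maps to undefined ROI '", nm, "'")
    }
  }
  if (identical(spec$loader, "toynet") && !is.null(spec$input$plane_shape)) {
    net <- toynet_load_h5(spec$weights_ref)
    if (!identical(as.integer(net$input_shape[1:2]),
                   as.integer(spec$input$plane_shape)))
      va_stop("shape", "metadata plane_shape ",
              paste(spec$input$plane_shape, collapse = "x"),
              " does not match model input ",
              paste(net$input_shape[1:2], collapse = "x"))
  }
  prior <- registry$entries[[spec$name]] %||% list()
  held <- if (length(prior))
    max(vapply(prior, `[[`, 0L, "version")) else 0L
  # auto-increment past the held versions, but honour a higher declared
  # version (pushed bundles carry their own numbering)
  spec$version <- max(held + 1L, spec$version)
  registry$entries[[spec$name]] <- c(prior, list(spec))
  registry$active[[spec$name]] <- spec$version
  invisible(spec)
}

#' Fetch the active (or a specific) version of a model
#'
#' @inheritParams import_model
#' @param name model name.
#' @param version optional version; default the active one.
#' @export
get_model <- function(registry, name, version = NULL) {
  entries <- registry$entries[[name]]
  if (is.null(entries)) va_stop("lookup", "unknown model: '", name, "'")
  v <- version %||% registry$active[[name]]
  hit <- which(vapply(entries, `[[`, 0L, "version") == v)
  if (!length(hit))
    va_stop("lookup", "model '", name, "' has no version ", v)
  entries[[hit[1]]]
}

#' Discover model bundles in a directory
#'
#' Scans for `*.model.yaml` metadata sidecars (each naming its weights file),
#' importing any bundle whose name is new to the registry or whose metadata
#' declares a higher version than the registry holds. Malformed bundles are
#' skipped with a report, not fatal. Re-scanning an unchanged directory
#' imports nothing.
#'
#' @inheritParams import_model
#' @param directory watched directory.
#' @return invisibly, a list with `imported` specs and `skipped` file names.
#' @export
discover_models <- function(registry, directory, project = NULL) {
  files <- list.files(directory, pattern = "\\.model\\.yaml$",
                      full.names = TRUE)
  imported <- list(); skipped <- character(0)
  for (f in files) {
    spec <- tryCatch(read_model_metadata(f), error = function(e) NULL)
    if (is.null(spec)) { skipped <- c(skipped, basename(f)); next }
    prior <- registry$entries[[spec$name]] %||% list()
    have <- if (length(prior)) max(vapply(prior, `[[`, 0L, "version")) else 0L
    declared <- spec$version
    if (declared > have) {
      ok <- tryCatch({ import_model(registry, spec, project); TRUE },
                     error = function(e) FALSE)
      if (ok) imported <- c(imported, list(spec))
      else skipped <- c(skipped, basename(f))
    }
  }
  invisible(list(imported = imported, skipped = skipped))
}

#' Write / read model metadata sidecars
#'
#' The YAML sidecar sits next to the HDF5 weights and fully describes how to
#' run the model.
#'
#' @param spec a `voxann_model_spec`.
#' @param path sidecar path (conventionally `<name>.model.yaml`).
#' @export
write_model_metadata <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_metadata
#' @export
read_model_metadata <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$name) || is.null(m$weights_ref) || is.null(m$input) ||
      is.null(m$output))
    va_stop("validation", "malformed model metadata: ", path)
  wref <- m$weights_ref
  if (!file.exists(wref))
    wref <- file.path(dirname(path), basename(wref))
  spec <- model_spec(m$name, wref, m$input,
                     m$normalization %||% list(method = "none"),
                     m$output, m$loader %||% "toynet",
                     m$version %||% 1L)
  spec
}

# ---- preprocessing -----------------------------------------------------------

apply_affine_op <- function(x, op) {
  if (is.list(op)) { nm <- op[[1]]; arg <- op[-1] } else { nm <- op; arg <- list() }
  ch <- function(f) {
    if (length(dim(x)) == 3) {
      out <- x
      for (c in seq_len(dim(x)[3])) out[, , c] <- f(x[, , c])
      out
    } else f(x)
  }
  switch(nm,
         flip_x = ch(function(m) m[nrow(m):1, , drop = FALSE]),
         flip_y = ch(function(m) m[, ncol(m):1, drop = FALSE]),
         rot90 = {
           k <- if (!is.null(arg$k)) arg$k else
             if (length(arg)) arg[[1]] else 1
           k <- k %% 4
           out <- x
           for (i in seq_len(k)) {
             out <- if (length(dim(out)) == 3) {
               d <- dim(out)
               new <- array(0, c(d[2], d[1], d[3]))
               for (c in seq_len(d[3]))
                 new[, , c] <- t(out[, , c])[ncol(out[, , c]):1, ,
                                             drop = FALSE]
               new
             } else t(out)[ncol(out):1, , drop = FALSE]
           }
           out
         },
         scale_to_shape = {
           shp <- unlist(arg)
           ch(function(m) bilinear_resize(m, shp[1], shp[2]))
         },
         va_stop("validation", "unknown affine op: ", nm))
}

invert_affine_op <- function(op) {
  if (is.list(op)) { nm <- op[[1]] } else nm <- op
  switch(nm,
         flip_x = "flip_x",
         flip_y = "flip_y",
         rot90 = {
           k <- 1
           if (is.list(op)) {
             k <- if (!is.null(op$k)) op$k else
               if (length(op) > 1) op[[2]] else 1
           }
           list("rot90", k = (4 - (k %% 4)) %% 4)
         },
         scale_to_shape = NULL)   # handled by resizing back to section shape
}

normalize_section <- function(x, normalization) {
  m <- normalization$method
  if (m == "none") return(x)
  if (m == "minmax") {
    r <- range(x)
    if (r[1] == r[2]) {
      va_warn("numeric", "constant section under minmax; returning zeros")
      return(x * 0)
    }
    (x - r[1]) / (r[2] - r[1])
  } else if (m == "zscore") {
    s <- stats::sd(as.numeric(x))
    if (s == 0) {
      va_warn("numeric", "zero-variance section under zscore; returning zeros")
      return(x * 0)
    }
    (x - mean(x)) / s
  } else {
    w <- unlist(normalization$window %||% normalization$params)
    pmin(pmax((x - w[1]) / (w[2] - w[1]), 0), 1)
  }
}

#' Preprocess an image section for a model
#'
#' Applies the spec's spatial ops in order, then its normalization.
#'
#' @param section 2-D matrix (or H x W x C array) in image space.
#' @param spec a `voxann_model_spec`.
#' @return the model-input array.
#' @export
preprocess <- function(section, spec) {
  x <- section
  for (op in spec$input$affine_ops %||% list()) x <- apply_affine_op(x, op)
  normalize_section(x, spec$normalization)
}

# Map a model-space label plane back to section space by undoing the spatial
# ops in reverse order (nearest-neighbour for the resize).
postprocess_labels <- function(plane, spec, section_dim) {
  ops <- rev(spec$input$affine_ops %||% list())
  for (op in ops) {
    inv <- invert_affine_op(op)
    if (is.null(inv)) plane <- nearest_resize(plane, section_dim[1],
                                              section_dim[2])
    else plane <- apply_affine_op(plane, inv)
  }
  plane
}

bilinear_resize <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  # align centers: coarse position of fine pixel i is (i-0.5)*n/nf + 0.5
  ri <- (seq_len(nr) - 0.5) * nrow(m) / nr + 0.5
  ci <- (seq_len(nc) - 0.5) * ncol(m) / nc + 0.5
  r0 <- pmin(pmax(floor(ri), 1), nrow(m)); r1 <- pmin(r0 + 1, nrow(m))
  c0 <- pmin(pmax(floor(ci), 1), ncol(m)); c1 <- pmin(c0 + 1, ncol(m))
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  m00 <- m[r0, c0, drop = FALSE]; m10 <- m[r1, c0, drop = FALSE]
  m01 <- m[r0, c1, drop = FALSE]; m11 <- m[r1, c1, drop = FALSE]
  FR <- matrix(fr, nr, nc); FC <- matrix(fc, nr, nc, byrow = TRUE)
  m00 * (1 - FR) * (1 - FC) + m10 * FR * (1 - FC) +
    m01 * (1 - FR) * FC + m11 * FR * FC
}

nearest_resize <- function(m, nr, nc) {
  ri <- pmin(pmax(round((seq_len(nr) - 0.5) * nrow(m) / nr + 0.5), 1),
             nrow(m))
  ci <- pmin(pmax(round((seq_len(nc) - 0.5) * ncol(m) / nc + 0.5), 1),
             ncol(m))
  m[ri, ci, drop = FALSE]
}

# ---- inference ---------------------------------------------------------------

slice_along <- function(vol, axis, i) {
  switch(axis,
         axial = vol[, , i],
         coronal = vol[, i, ],
         sagittal = vol[i, , ])
}

n_slices <- function(vol, axis) {
  switch(axis, axial = dim(vol)[3], coronal = dim(vol)[2],
         sagittal = dim(vol)[1])
}

decide_labels <- function(scores, rule, threshold = 0.5) {
  # scores: H x W x C; class 1 (R index) is background
  if (rule == "argmax") {
    apply(scores, c(1, 2), which.max) - 1L
  } else {
    nC <- dim(scores)[3]
    lab <- matrix(0L, dim(scores)[1], dim(scores)[2])
    for (cls in 2:nC) {
      sel <- scores[, , cls] >= threshold & lab == 0L
      lab[sel] <- cls - 1L
    }
    lab
  }
}

# Positions of patches of length p at stride s covering 1..n (last patch
# snapped to the end).
patch_starts <- function(n, p, s) {
  if (p >= n) return(1L)
  st <- seq(1L, n - p + 1L, by = s)
  if (st[length(st)] != n - p + 1L) st <- c(st, n - p + 1L)
  st
}

# Separable raised-cosine blending window with a floor so border voxels
# covered by a single patch keep nonzero weight; per-voxel weights are
# normalised to sum to one across overlapping patches.
cosine_window <- function(p) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(p) - 0.5) / p)
  w + 1e-3
}

#' Run a model over a series and draft annotations
#'
#' 2-D mode slices the volume along the spec's axis, preprocesses and
#' predicts each slice, and maps class labels back to ROI bits. Patch-wise
#' 3-D mode tiles the volume with stride = patch/2 per axis and blends
#' per-class scores with normalised cosine-window weights (summing to one at
#' every voxel) before applying the decision rule. All produced (slice, ROI)
#' provenance is auto. Classification writes the mapped text value instead.
#'
#' @inheritParams apply_edit
#' @param spec a `voxann_model_spec`.
#' @return segmentation: the updated label volume (invisibly);
#'   classification: the mapped `c(field, value)` character vector.
#' @export
infer <- function(project, series, spec, user = NULL) {
  loader <- get_model_loader(spec$loader)
  predict_fn <- loader(spec$weights_ref)
  img <- series_image(project, series)
  mapping <- spec$output$mapping
  if (spec$output$task == "segmentation") {
    defs <- lapply(unlist(mapping), function(nm) roi_get(project, nm))
    for (d in defs) if (d$locked)
      va_stop("locked_roi", "target ROI '", d$name, "' is locked")
    if (!is.null(project$workflow) && !can_edit(project, user, series))
      va_stop("permission", "user does not hold series '", series, "'")
  }
  if (spec$input$mode == "2d") {
    if (spec$output$task == "classification") {
      # classify the mid slice stack: average class scores over slices
      axis <- spec$input$axis
      ns <- n_slices(img, axis)
      acc <- NULL
      for (i in seq_len(ns)) {
        x <- preprocess(slice_along(img, axis, i), spec)
        sc <- predict_fn(x)
        acc <- if (is.null(acc)) sc else acc + sc
      }
      cls <- which.max(acc)
      tv <- mapping[[as.character(cls - 1L)]] %||% mapping[[cls]]
      if (is.null(tv)) va_stop("validation", "no mapping for class ",
                               cls - 1L)
      set_text_value(project, series, tv[[1]], tv[[2]])
      return(invisible(unlist(tv)))
    }
    axis <- spec$input$axis
    if (axis != "axial")
      va_stop("validation",
              "segmentation drafting supports the axial axis")
    lv <- get_label_volume(project, series)
    snap <- labels_snapshot(lv)
    nz <- dim(img)[3]
    for (z in seq_len(nz)) {
      sec <- img[, , z]
      x <- preprocess(sec, spec)
      scores <- predict_fn(x)
      if (length(dim(scores)) != 3)
        va_stop("validation", "segmentation model must return H x W x C ",
                "scores")
      if (dim(scores)[3] < length(mapping) + 1)
        va_stop("validation", "model output channels (", dim(scores)[3],
                ") do not cover the mapping")
      lab <- decide_labels(scores, spec$output$rule,
                           spec$output$threshold %||% 0.5)
      lab <- postprocess_labels(lab, spec, dim(sec))
      word <- lv$labels[, , z]
      for (ci in names(mapping)) {
        def <- roi_get(project, mapping[[ci]])
        sel <- lab == as.integer(ci)
        if (project$exclusive_mode) word[sel] <- def$mask_value
        else word[sel] <- bit_set(word[sel], def$mask_value)
        if (any(sel)) lv <- set_provenance(lv, z - 1L, def$mask_value,
                                           "auto")
      }
      lv$labels[, , z] <- word
    }
    set_label_volume(project, series, lv)
    push_history(project, series, snap)
    return(invisible(lv))
  }
  # ---- 3d_patch --------------------------------------------------------------
  p <- as.integer(spec$input$patch_shape)
  d <- dim(img)
  p <- pmin(p, d)
  s <- pmax(p %/% 2L, 1L)
  nC <- NULL
  win <- outer(outer(cosine_window(p[1]), cosine_window(p[2])),
               cosine_window(p[3]))
  acc <- NULL; wsum <- array(0, d)
  for (sx in patch_starts(d[1], p[1], s[1]))
    for (sy in patch_starts(d[2], p[2], s[2]))
      for (sz in patch_starts(d[3], p[3], s[3])) {
        patch <- img[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1),
                     sz:(sz + p[3] - 1), drop = FALSE]
        x <- normalize_section(patch, spec$normalization)
        sc <- predict_fn(x)   # p1 x p2 x p3 x C
        if (is.null(acc)) {
          nC <- dim(sc)[4]
          acc <- array(0, c(d, nC))
        }
        for (cls in seq_len(nC)) {
          acc[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1), sz:(sz + p[3] - 1),
              cls] <-
            acc[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1), sz:(sz + p[3] - 1),
                cls] + sc[, , , cls] * win
        }
        wsum[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1), sz:(sz + p[3] - 1)] <-
          wsum[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1),
               sz:(sz + p[3] - 1)] + win
      }
  for (cls in seq_len(nC)) acc[, , , cls] <- acc[, , , cls] / wsum
  lv <- get_label_volume(project, series)
  snap <- labels_snapshot(lv)
  lab <- array(0L, d)
  if (spec$output$rule == "argmax") {
    best <- acc[, , , 1]; lab <- array(0L, d)
    if (nC > 1) for (cls in 2:nC) {
      better <- acc[, , , cls] > best
      lab[better] <- cls - 1L
      best[better] <- acc[, , , cls][better]
    }
  } else {
    thr <- spec$output$threshold %||% 0.5
    for (cls in 2:nC) lab[acc[, , , cls] >= thr & lab == 0L] <- cls - 1L
  }
  for (ci in names(mapping)) {
    def <- roi_get(project, mapping[[ci]])
    sel <- lab == as.integer(ci)
    if (project$exclusive_mode) lv$labels[sel] <- def$mask_value
    else lv$labels[sel] <- bit_set(lv$labels[sel], def$mask_value)
    zs <- unique(which(sel, arr.ind = TRUE)[, 3]) - 1L
    lv <- set_provenance(lv, zs, def$mask_value, "auto")
  }
  set_label_volume(project, series, lv)
  push_history(project, series, snap)
  invisible(lv)
}

# Per-voxel blend weights for a volume/patch layout; exported for inspection
# and testing of the partition-of-unity property.

#' Patch-blending weights for a volume
#'
#' Returns the per-voxel normalised blending weights of every patch position
#' used by patch-wise 3-D inference; summing the returned array over patches
#' gives exactly one at every voxel.
#'
#' @param vol_shape volume shape (X, Y, Z).
#' @param patch_shape patch shape.
#' @return list with `starts` (matrix of patch origins) and `weights`
#'   (list of normalised weight arrays, one per patch).
#' @export
blend_weights <- function(vol_shape, patch_shape) {
  d <- as.integer(vol_shape)
  p <- pmin(as.integer(patch_shape), d)
  s <- pmax(p %/% 2L, 1L)
  win <- outer(outer(cosine_window(p[1]), cosine_window(p[2])),
               cosine_window(p[3]))
  starts <- as.matrix(expand.grid(x = patch_starts(d[1], p[1], s[1]),
                                  y = patch_starts(d[2], p[2], s[2]),
                                  z = patch_starts(d[3], p[3], s[3])))
  wsum <- array(0, d)
  for (i in seq_len(nrow(starts))) {
    sx <- starts[i, 1]; sy <- starts[i, 2]; sz <- starts[i, 3]
    wsum[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1), sz:(sz + p[3] - 1)] <-
      wsum[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1), sz:(sz + p[3] - 1)] + win
  }
  weights <- lapply(seq_len(nrow(starts)), function(i) {
    sx <- starts[i, 1]; sy <- starts[i, 2]; sz <- starts[i, 3]
    win / wsum[sx:(sx + p[1] - 1), sy:(sy + p[2] - 1), sz:(sz + p[3] - 1)]
  })
  list(starts = starts, weights = weights, shape = d, patch = p)
}
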