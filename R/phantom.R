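# Synthetic phantom volumes with exact ground truth. Ellipsoidal foreground
# objects at a foreground mean intensity over background, with additive
# Gaussian noise; the truth labels are the noiseless ellipsoid interiors.
# Identical seed + config gives bit-identical output, which every other
# module's tests rely on.

#' Phantom generator configuration
#'
#' @param shape voxel extents (X, Y, Z).
#' @param n_objects number of ellipsoids.
#' @param radius_range `c(min, max)` semi-axis range in voxels.
#' @param fg_intensity,bg_intensity mean intensities inside/outside objects.
#' @param noise_sigma SD of additive Gaussian noise.
#' @param seed RNG seed; same seed + config reproduces the phantom exactly.
#' @return a config list for [generate_phantom()].
#' @export
phantom_config <- function(shape = c(32L, 32L, 32L), n_objects = 1L,
                           radius_range = c(4, 8), fg_intensity = 100,
                           bg_intensity = 0, noise_sigma = 20, seed = 1L) {
  if (any(shape < 4)) va_stop("validation", "degenerate phantom shape")
  if (2 * max(radius_range) + 2 > min(shape))
    va_stop("validation", "radii do not fit within the phantom shape")
  list(shape = as.integer(shape), n_objects = as.integer(n_objects),
       radius_range = radius_range, fg_intensity = fg_intensity,
       bg_intensity = bg_intensity, noise_sigma = noise_sigma,
       seed = as.integer(seed))
}

#' Generate a phantom volume with ground-truth labels
#'
#' @param config a [phantom_config()].
#' @return list with `image` (noisy intensity array) and `truth` (logical
#'   array of the exact noiseless object interiors).
#' @export
generate_phantom <- function(config) {
  d <- config$shape
  rng <- config$radius_range
  set.seed(config$seed)
  truth <- array(FALSE, d)
  gx <- seq_len(d[1]); gy <- seq_len(d[2]); gz <- seq_len(d[3])
  for (i in seq_len(config$n_objects)) {
    r <- stats::runif(3, rng[1], rng[2])
    ctr <- vapply(1:3, function(a) stats::runif(1, r[a] + 1, d[a] - r[a]),
                  0)
    ex <- outer(outer(((gx - ctr[1]) / r[1])^2, ((gy - ctr[2]) / r[2])^2,
                      "+"), ((gz - ctr[3]) / r[3])^2, "+")
    truth <- truth | (ex <= 1)
  }
  img <- array(config$bg_intensity, d)
  img[truth] <- config$fg_intensity
  if (config$noise_sigma > 0)
    img <- img + array(stats::rnorm(prod(d), 0, config$noise_sigma), d)
  list(image = img, truth = truth)
}

#' Write a phantom suite as NIfTI files
#'
#' @param configs list of [phantom_config()]s.
#' @param dir output directory; each phantom writes `phantom_<i>.nii.gz` and
#'   `phantom_<i>_truth.nii.gz`.
#' @export
write_phantom_suite <- function(configs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(configs)) {
    ph <- generate_phantom(configs[[i]])
    f <- file.path(dir, sprintf("phantom_%03d.nii.gz", i))
    RNifti::writeNifti(make_nifti(ph$image, diag(4)), f)
    ft <- file.path(dir, sprintf("phantom_%03d_truth.nii.gz", i))
    RNifti::writeNifti(make_nifti(ph$truth * 1, diag(4)), ft,
                       datatype = "uint8")
    paths <- c(paths, f)
  }
  invisible(paths)
}
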