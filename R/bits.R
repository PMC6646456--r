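# Label grids are "bit words" stored as doubles: each voxel's value is the sum
# (bitwise OR) of the mask values of the ROIs labelling it. Mask values are
# distinct powers of two, so a double represents any combination exactly as
# long as no bit exceeds 2^52 (the mantissa limit). The project therefore caps
# ROI definitions at bit 52, i.e. 53 ROIs per export word.

VOXANN_MAX_BIT_EXP <- 52L

#' Test, set and clear ROI bits in a label word
#'
#' Vectorised exact bit arithmetic on label words stored as doubles.
#' `mask_value` must be a single power of two not exceeding 2^52.
#'
#' @param x numeric vector/array of label words (nonnegative integers stored
#'   as doubles).
#' @param mask_value a single power of two identifying one ROI's bit plane.
#' @return `bit_test` a logical vector/array; `bit_set`/`bit_clear` the
#'   updated words.
#' @keywords internal
bit_test <- function(x, mask_value) {
  (x %/% mask_value) %% 2 == 1
}

#' @rdname bit_test
#' @keywords internal
bit_set <- function(x, mask_value) {
  x + mask_value * !bit_test(x, mask_value)
}

#' @rdname bit_test
#' @keywords internal
bit_clear <- function(x, mask_value) {
  x - mask_value * bit_test(x, mask_value)
}

# Number of set bits per word, counting only bits 0..52.
bit_popcount <- function(x) {
  n <- array(0, dim = dim(x) %||% length(x))
  for (k in 0:VOXANN_MAX_BIT_EXP) {
    b <- 2^k
    if (all(x < b)) break
    n <- n + ((x %/% b) %% 2)
  }
  n
}

# Decompose the set of bits present anywhere in x into their mask values.
bits_present <- function(x) {
  mx <- max(x, 0)
  out <- numeric(0)
  k <- 0
  while (2^k <= mx && k <= VOXANN_MAX_BIT_EXP) {
    if (any(bit_test(x, 2^k))) out <- c(out, 2^k)
    k <- k + 1
  }
  out
}

is_power_of_two <- function(v) {
  is.numeric(v) && length(v) == 1 && v >= 1 &&
    abs(log2(v) - round(log2(v))) < 1e-9
}
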