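# Preprocessing: raw counts -> classifier-ready inputs.
#
# The online pipeline applies, per acquired (y, lambda) slice:
#   1. white/dark reflectance normalization (subunitary values),
#   2. 7 x 7 2-D median filtering (removes fiber-cladding impulse artifacts),
#   3. binning of the spectral axis to 121 equispaced samples,
#   4. wrapping of each pixel's binned spectrum into an 11 x 11 patch.

# broadcast a (y, lambda) calibration frame against cube slice x
.cal_slice <- function(frame, x) {
  if (length(dim(frame)) == 3L) frame[x, , ] else frame
}

#' Normalize raw counts to reflectance
#'
#' Computes `(I - I_dark) / (I_white - I_dark)` elementwise and clips the
#' result to \[0, 1\] (specular out-of-range pixels are clipped, not
#' rejected). Pixels where the white reference does not exceed the dark frame
#' are set to 0 and counted in the `flagged` metadata field.
#'
#' @param cube a [hypercube()] of raw counts.
#' @param cal a [calibration_frames()] pair, `(y, lambda)` frames broadcast
#'   across scan steps or full `(x, y, lambda)` arrays.
#' @return a [hypercube()] of reflectance in \[0, 1\]; `meta$flagged` holds
#'   the number of degenerate calibration elements encountered.
#' @export
normalize_reflectance <- function(cube, cal) {
  stopifnot(inherits(cube, "hypercube"), inherits(cal, "calibration_frames"))
  d <- dim(cube$data)
  cd <- dim(cal$white)
  if (length(cd) == 2L) {
    if (!identical(cd, d[2:3])) stop("calibration frame shape does not match cube (y, lambda)")
  } else if (!identical(cd, d)) {
    stop("calibration cube shape does not match data cube")
  }
  denom <- cal$white - cal$dark
  bad <- denom <= 0
  out <- array(0, dim = d)
  for (x in seq_len(d[1L])) {
    w <- .cal_slice(cal$white, x)
    dk <- .cal_slice(cal$dark, x)
    dn <- .cal_slice(denom, x)
    bd <- .cal_slice(bad, x)
    sl <- (cube$data[x, , ] - dk) / dn
    sl[bd] <- 0
    out[x, , ] <- pmin(pmax(sl, 0), 1)
  }
  meta <- cube$meta
  meta$flagged <- sum(bad)
  meta$normalized <- TRUE
  hypercube(out, cube$wavelengths, meta)
}

#' 7 x 7 2-D median filter
#'
#' Applied to each `(y, lambda)` slice independently, so the identical
#' operator serves both online single-slice and offline whole-cube use.
#' Edges are handled by symmetric (reflective) padding.
#'
#' @param x a [hypercube()] or a 2-D `(y, lambda)` matrix.
#' @param size odd window edge length (default 7).
#' @return same type and shape as `x`.
#' @export
median_denoise <- function(x, size = 7L) {
  if (inherits(x, "hypercube")) {
    out <- x$data
    for (i in seq_len(dim(x$data)[1L])) {
      out[i, , ] <- .median_filter_2d(x$data[i, , , drop = TRUE], as.integer(size))
    }
    return(hypercube(out, x$wavelengths, x$meta))
  }
  if (!is.matrix(x)) stop("x must be a hypercube or a 2-D matrix")
  .median_filter_2d(x, as.integer(size))
}

# contiguous near-equal partition of 1..len into n_bins ranges
.bin_groups <- function(len, n_bins) {
  base <- len %/% n_bins
  rem <- len %% n_bins
  rep(seq_len(n_bins), times = base + (seq_len(n_bins) <= rem))
}

#' Bin a spectrum to a fixed number of equispaced samples
#'
#' Partitions the spectral axis into `n_bins` contiguous index ranges whose
#' lengths differ by at most one and averages within each range. Binning by
#' averaging makes classifiers robust to the native spectral resolution of
#' the grating in use.
#'
#' @param spectrum numeric vector (length >= `n_bins`).
#' @param n_bins output length (default 121).
#' @return numeric vector of length `n_bins`.
#' @export
bin_spectrum <- function(spectrum, n_bins = 121L) {
  len <- length(spectrum)
  if (len < n_bins) {
    stop(sprintf("spectrum length (%d) is below n_bins (%d); upsampling is not supported",
                 len, n_bins))
  }
  g <- .bin_groups(len, n_bins)
  as.numeric(tapply(spectrum, g, mean))
}

# bin all rows of a (pixels x lambda) matrix at once via a grouping operator
.bin_matrix <- function(m, n_bins = 121L) {
  len <- ncol(m)
  if (len < n_bins) stop("spectral axis shorter than n_bins")
  g <- .bin_groups(len, n_bins)
  B <- Matrix::sparseMatrix(i = seq_len(len), j = g,
                            x = 1 / tabulate(g)[g], dims = c(len, n_bins))
  as.matrix(m %*% B)
}

#' Wrap a binned spectrum into an 11 x 11 spectral patch
#'
#' Row-major fill: sample `k` (0-based) goes to row `k %/% 11`, column
#' `k %% 11` (0-based). The fixed bijection lets a 2-D convolutional network
#' consume single-pixel spectra.
#'
#' @param binned numeric vector of length exactly 121.
#' @param origin optional `(x, y)` source pixel coordinates.
#' @return an 11 x 11 matrix of class `spectral_patch`.
#' @export
wrap_patch <- function(binned, origin = c(NA_integer_, NA_integer_)) {
  if (length(binned) != 121L) {
    stop(sprintf("patch wrapping requires exactly 121 samples, got %d", length(binned)))
  }
  p <- matrix(as.numeric(binned), 11L, 11L, byrow = TRUE)
  structure(p, class = c("spectral_patch", "matrix", "array"), origin = origin)
}

#' Unwrap a spectral patch back to its 121-sample spectrum
#' @param patch an 11 x 11 `spectral_patch` (or plain matrix).
#' @return numeric vector of length 121; exact inverse of [wrap_patch()].
#' @export
unwrap_patch <- function(patch) {
  if (!all(dim(patch) == c(11L, 11L))) stop("patch must be 11 x 11")
  as.numeric(t(unclass(patch)))
}

# slice-level normalization against (y, lambda) frames
.normalize_slice <- function(slice, white, dark) {
  denom <- white - dark
  out <- (slice - dark) / denom
  out[denom <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Preprocess one (y, lambda) slice into spectral patches
#'
#' Composition of the full online chain: normalize, median-filter, bin, wrap
#' — one patch per line pixel. Wall-clock preprocessing time is recorded
#' (preprocessing dominates the online frame budget, so it is tracked
#' explicitly for frames-per-second accounting).
#'
#' @param slice numeric `(y, lambda)` matrix of raw counts.
#' @param cal a [calibration_frames()] with `(y, lambda)` frames.
#' @param n_bins spectral bin count (default 121; patch wrapping requires
#'   121).
#' @param median_size median filter window (default 7).
#' @return list of `spectral_patch` objects (one per line pixel) with
#'   attributes `binned` (the `(y, n_bins)` matrix) and
#'   `preprocess_seconds`.
#' @export
prepare_slice <- function(slice, cal, n_bins = 121L, median_size = 7L) {
  stopifnot(is.matrix(slice), inherits(cal, "calibration_frames"))
  t0 <- proc.time()[["elapsed"]]
  norm <- .normalize_slice(slice, cal$white, cal$dark)
  den <- .median_filter_2d(norm, as.integer(median_size))
  binned <- .bin_matrix(den, n_bins)
  patches <- lapply(seq_len(nrow(binned)), function(i) {
    wrap_patch(binned[i, ], origin = c(NA_integer_, i))
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  attr(patches, "binned") <- binned
  attr(patches, "preprocess_seconds") <- elapsed
  patches
}

#' Preprocess a whole hypercube
#'
#' Offline analogue of [prepare_slice()]: normalization, per-slice median
#' filtering and spectral binning for every scan step at once.
#'
#' @param cube a [hypercube()] of raw counts.
#' @param cal a [calibration_frames()].
#' @param n_bins spectral bin count (default 121).
#' @param median_size median filter window (default 7).
#' @return list with `binned` (matrix of `nx * ny` rows in `(x, y)`
#'   column-major pixel order by `n_bins` columns) and `dim` (`c(nx, ny)`).
#' @export
preprocess_cube <- function(cube, cal, n_bins = 121L, median_size = 7L) {
  norm <- normalize_reflectance(cube, cal)
  den <- median_denoise(norm, size = median_size)
  d <- dim(den$data)
  flat <- den$data
  dim(flat) <- c(d[1L] * d[2L], d[3L])
  # rows of `flat` follow column-major (x, y) order only after interleaving
  # slices correctly: array dim collapse keeps x fastest, which is what we want
  binned <- .bin_matrix(flat, n_bins)
  list(binned = binned, dim = d[1:2])
}
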