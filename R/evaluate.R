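# Quantitative evaluation and operator-facing rendering.
#
# The headline metric is the average classification accuracy ACC_av:
# both label maps are one-hot encoded over the 19 classes, the per-pixel
# disagreement indicator is the maximum over the class dimension of the
# absolute one-hot difference (1 exactly when the labels differ), and
# ACC_av = (1 - sum(disagreements) / N) * 100.

#' Average classification accuracy (ACC_av) of a prediction map
#'
#' @param E predicted [label_map()] (or integer matrix).
#' @param R reference [label_map()] (or integer matrix); same shape and
#'   legend as `E`.
#' @param n_classes number of classes for the one-hot encoding including
#'   background (default 19).
#' @param per_slice_seconds optional per-slice timing vector carried into
#'   the report.
#' @return an `evaluation_report`: `acc_av` (percent), `confusion`
#'   (reference x prediction count matrix), `n_pixels`, and (when timing is
#'   given) `per_slice_seconds` and `fps`.
#' @export
accuracy <- function(E, R, n_classes = 19L, per_slice_seconds = NULL) {
  Em <- if (inherits(E, "label_map")) E$labels else as.matrix(E)
  Rm <- if (inherits(R, "label_map")) R$labels else as.matrix(R)
  if (!identical(dim(Em), dim(Rm))) stop("prediction and reference shapes differ")
  if (inherits(E, "label_map") && inherits(R, "label_map") &&
      !identical(E$legend[order(names(E$legend))],
                 R$legend[order(names(R$legend))])) {
    stop("prediction and reference legends differ")
  }
  e <- as.vector(Em)
  r <- as.vector(Rm)
  if (max(c(e, r)) >= n_classes || min(c(e, r)) < 0L) {
    stop(sprintf("labels outside 0..%d", n_classes - 1L))
  }
  n <- length(e)
  # one-hot encode both maps (N x L) and take the max absolute difference
  # along the class dimension
  Eh <- matrix(0L, n, n_classes)
  Eh[cbind(seq_len(n), e + 1L)] <- 1L
  Rh <- matrix(0L, n, n_classes)
  Rh[cbind(seq_len(n), r + 1L)] <- 1L
  disagree <- apply(abs(Eh - Rh), 1L, max)
  acc <- (1 - sum(disagree) / n) * 100
  lev <- 0:(n_classes - 1L)
  confusion <- table(reference = factor(r, levels = lev),
                     prediction = factor(e, levels = lev))
  out <- list(acc_av = acc, confusion = confusion, n_pixels = n)
  if (!is.null(per_slice_seconds)) {
    out$per_slice_seconds <- per_slice_seconds
    out$fps <- 1 / mean(per_slice_seconds)
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> ACC_av = %.2f%% over %d pixels\n",
              x$acc_av, x$n_pixels))
  if (!is.null(x$fps)) cat(sprintf("  fps = %.2f (hardware-dependent)\n", x$fps))
  invisible(x)
}

#' Per-slice timing summary
#'
#' Summarizes measured per-slice classification times into achievable
#' frames-per-second. Timing is hardware-dependent and reported, never
#' asserted against published figures.
#'
#' @param results list of `classification_result` objects (or a numeric
#'   vector of per-slice seconds).
#' @return list with `mean_seconds`, `median_seconds`, `max_seconds`, `fps`.
#' @export
timing_report <- function(results) {
  secs <- if (is.numeric(results)) results else
    vapply(results, function(r) r$per_slice_seconds, numeric(1L))
  if (length(secs) == 0L) stop("no per-slice timings supplied")
  list(
    mean_seconds = mean(secs),
    median_seconds = stats::median(secs),
    max_seconds = max(secs),
    fps = 1 / mean(secs)
  )
}

#' Render a label map as an RGB image
#'
#' Colors come from the library's per-class display codes; background is
#' rendered black.
#'
#' @param labels a [label_map()], integer matrix, or `classification_result`
#'   vector reshaped by `dim`.
#' @param library a [reference_library()].
#' @param dim optional `c(nx, ny)` when `labels` is a bare vector.
#' @return numeric array `(nx, ny, 3)` of RGB values in \[0, 1\].
#' @export
render_prediction_map <- function(labels, library, dim = NULL) {
  stopifnot(inherits(library, "reference_library"))
  m <- if (inherits(labels, "label_map")) labels$labels
  else if (inherits(labels, "classification_result")) {
    matrix(labels$labels, nrow = 1L)
  } else if (is.matrix(labels)) labels
  else matrix(labels, dim[1L], dim[2L])
  if (max(m) > nrow(library$rgb) || min(m) < 0L) {
    stop("label map contains labels unknown to the library")
  }
  lut <- rbind(c(0, 0, 0), library$rgb)   # row 1 = background (black)
  img <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(lut[m + 1L, ch], nrow(m), ncol(m))
  img
}

#' Overlay a classified line on a wide-field image
#'
#' Paints the class colors of one classified slice into the image row it was
#' acquired from, leaving every other pixel untouched — the real-time
#' operator display of the line-scanning system.
#'
#' @param wide_field numeric array `(nx, ny, 3)` RGB in \[0, 1\].
#' @param slice_result a `classification_result` (labels of length `ny`).
#' @param line_position row index (scan position) of the slice.
#' @param library a [reference_library()].
#' @param tint_background if `FALSE` (default), background-class pixels on
#'   the line keep the underlying image.
#' @return the overlaid RGB array.
#' @export
render_line_overlay <- function(wide_field, slice_result, line_position,
                                library, tint_background = FALSE) {
  stopifnot(length(dim(wide_field)) == 3L, dim(wide_field)[3L] == 3L)
  labels <- if (inherits(slice_result, "classification_result"))
    slice_result$labels else as.integer(slice_result)
  if (line_position < 1L || line_position > dim(wide_field)[1L]) {
    stop("line position outside the image")
  }
  if (length(labels) != dim(wide_field)[2L]) {
    stop("slice length does not match the image width")
  }
  lut <- rbind(c(0, 0, 0), library$rgb)
  out <- wide_field
  keep <- labels == 0L & !tint_background
  for (ch in 1:3) {
    row <- lut[labels + 1L, ch]
    row[keep] <- wide_field[line_position, keep, ch]
    out[line_position, , ch] <- row
  }
  out
}

#' Write an RGB array as a PNG file
#' @param img numeric array `(nx, ny, 3)` in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(aperm(img, c(1L, 2L, 3L)), path)
  invisible(path)
}

#' Decode an RGB rendering back to labels by nearest display color
#'
#' Inverse lookup of [render_prediction_map()]: each pixel is assigned the
#' class whose display RGB is nearest in Euclidean distance (background
#' black included).
#'
#' @param img numeric array `(nx, ny, 3)`.
#' @param library a [reference_library()].
#' @return integer label matrix.
#' @export
decode_rgb_labels <- function(img, library) {
  lut <- rbind(c(0, 0, 0), library$rgb)
  d <- dim(img)
  flat <- matrix(img, d[1L] * d[2L], 3L)
  d2 <- outer(rowSums(flat^2), rowSums(lut^2), "+") - 2 * flat %*% t(lut)
  matrix(max.col(-d2, ties.method = "first") - 1L, d[1L], d[2L])
}

#' Downsample a high-resolution reference to the classification grid
#'
#' Block-mode (majority-label) downsampling: the source grid is partitioned
#' into contiguous blocks matching the target shape and each target pixel
#' takes the most frequent source label in its block, ties breaking to the
#' lowest label.
#'
#' @param reference a [label_map()], an integer label matrix, or an RGB
#'   array (decoded via [decode_rgb_labels()], in which case `library` is
#'   required).
#' @param target_shape integer `c(nx, ny)`, elementwise no larger than the
#'   source.
#' @param library optional [reference_library()] for RGB input.
#' @param legend legend for the output map (defaults to the input's).
#' @return a [label_map()] of shape `target_shape`.
#' @export
downsample_reference <- function(reference, target_shape, library = NULL,
                                 legend = NULL) {
  m <- if (inherits(reference, "label_map")) {
    if (is.null(legend)) legend <- reference$legend
    reference$labels
  } else if (is.array(reference) && length(dim(reference)) == 3L) {
    if (is.null(library)) stop("RGB reference input requires a library")
    decode_rgb_labels(reference, library)
  } else as.matrix(reference)
  if (any(target_shape > dim(m))) {
    stop("target shape exceeds the source shape")
  }
  gx <- .bin_groups(nrow(m), target_shape[1L])
  gy <- .bin_groups(ncol(m), target_shape[2L])
  out <- matrix(0L, target_shape[1L], target_shape[2L])
  for (i in seq_len(target_shape[1L])) {
    rows <- which(gx == i)
    for (j in seq_len(target_shape[2L])) {
      block <- m[rows, which(gy == j)]
      tab <- table(block)
      best <- as.integer(names(tab)[tab == max(tab)])
      out[i, j] <- min(best)
    }
  }
  if (is.null(legend)) {
    lev <- sort(unique(as.vector(out)))
    legend <- stats::setNames(as.character(lev), as.character(lev))
  }
  label_map(out, legend)
}
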