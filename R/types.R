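#' Hypercube constructor
#'
#' A hypercube is the central object of the line-scanning pipeline: a 3-D
#' reflectance (or raw-count) array indexed `(x, y, lambda)` where `x` is the
#' scan step (one per acquired slice), `y` the pixel along the measured line
#' and `lambda` the spectral channel, together with the wavelength axis and
#' free-form acquisition metadata.
#'
#' @param data numeric 3-D array indexed `(x, y, lambda)`; values must be
#'   non-negative.
#' @param wavelengths strictly increasing numeric vector (nm) with length equal
#'   to `dim(data)[3]`.
#' @param meta named list of free-form metadata (grating, exposure, ...).
#' @return object of class `hypercube` with fields `data`, `wavelengths`,
#'   `meta`.
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("hypercube 'data' must be a 3-D array indexed (x, y, lambda)")
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L]) {
    stop(sprintf(
      "wavelength vector length (%d) must equal the spectral extent (%d)",
      length(wavelengths), dim(data)[3L]
    ))
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (anyNA(data)) stop("hypercube data contains NA")
  if (min(data) < 0) stop("hypercube data must be non-negative")
  structure(
    list(data = data, wavelengths = wavelengths, meta = as.list(meta)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> (x, y, lambda) = (%d, %d, %d), %.1f-%.1f nm, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Calibration frame pair
#'
#' White and dark reference frames used by reflectance normalization. Frames
#' are `(y, lambda)` matrices (one calibration line, broadcast across scan
#' steps) or full `(x, y, lambda)` arrays shaped like the cube they calibrate.
#'
#' @param white numeric matrix or 3-D array of white-target counts.
#' @param dark numeric matrix or 3-D array of dark (sensor offset) counts,
#'   same shape as `white`.
#' @return object of class `calibration_frames`.
#' @export
calibration_frames <- function(white, dark) {
  if (!identical(dim(white), dim(dark))) {
    stop("white and dark frames must have identical shape")
  }
  nd <- length(dim(white))
  if (!nd %in% c(2L, 3L)) stop("calibration frames must be 2-D or 3-D arrays")
  structure(list(white = white, dark = dark), class = "calibration_frames")
}

#' Reference spectrum library
#'
#' Ordered set of named color classes, each holding a reference reflectance
#' spectrum on a common wavelength grid plus an RGB display code. Class labels
#' 1..n are the color classes; label 0 is reserved for the background class
#' (any spectrum matching no color).
#'
#' @param names character vector of unique class names.
#' @param spectra numeric matrix, one row per class, columns on `wavelengths`.
#' @param rgb numeric matrix `n x 3` of display colors in \[0, 1\].
#' @param wavelengths numeric grid (nm) the spectra are tabulated on.
#' @return object of class `reference_library` with fields `names`, `spectra`,
#'   `rgb`, `wavelengths`, `background_label` (always 0).
#' @export
reference_library <- function(names, spectra, rgb, wavelengths) {
  names <- as.character(names)
  spectra <- as.matrix(spectra)
  rgb <- as.matrix(rgb)
  if (anyDuplicated(names)) stop("class names must be unique")
  if (nrow(spectra) != length(names)) stop("one spectrum per class required")
  if (ncol(spectra) != length(wavelengths)) {
    stop("spectra and wavelength grid disagree in length")
  }
  if (!identical(dim(rgb), c(length(names), 3L)) &&
      !identical(dim(rgb), c(as.integer(length(names)), 3L))) {
    stop("rgb must be an n x 3 matrix")
  }
  if (min(spectra) < 0 || max(spectra) > 1) {
    stop("reference spectra must lie in [0, 1]")
  }
  structure(
    list(
      names = names, spectra = spectra, rgb = rgb,
      wavelengths = as.numeric(wavelengths), background_label = 0L
    ),
    class = "reference_library"
  )
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf(
    "<reference_library> %d classes on %d wavelengths (%.0f-%.0f nm) + background\n",
    length(x$names), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths)
  ))
  invisible(x)
}

#' Resample library spectra onto a new wavelength grid
#'
#' Linear interpolation of every class spectrum; values outside the tabulated
#' range take the nearest endpoint (reflectance varies slowly at the band
#' edges of the halogen illumination window).
#'
#' @param library a [reference_library()].
#' @param wavelengths target grid (nm), strictly increasing.
#' @return a `reference_library` on the new grid.
#' @export
resample_library <- function(library, wavelengths) {
  stopifnot(inherits(library, "reference_library"))
  sp <- t(apply(library$spectra, 1L, function(s) {
    stats::approx(library$wavelengths, s, xout = wavelengths, rule = 2)$y
  }))
  reference_library(library$names, sp, library$rgb, wavelengths)
}

#' Subset a reference library to selected classes
#'
#' Used by the four-color comparison protocol, where the conventional
#' classifiers match against only the classes present in the imaged section.
#' The returned library keeps an attribute `class_ids` mapping its rows back
#' to the original class labels.
#'
#' @param library a [reference_library()].
#' @param classes integer vector of original class labels to keep.
#' @return a `reference_library` over the selected classes.
#' @export
subset_library <- function(library, classes) {
  stopifnot(inherits(library, "reference_library"))
  classes <- as.integer(classes)
  if (any(classes < 1L) || any(classes > length(library$names))) {
    stop("classes outside the library")
  }
  out <- reference_library(library$names[classes],
                           library$spectra[classes, , drop = FALSE],
                           library$rgb[classes, , drop = FALSE],
                           library$wavelengths)
  attr(out, "class_ids") <- classes
  out
}

#' Per-pixel categorical label map
#'
#' @param labels integer matrix indexed `(x, y)`; values must appear in
#'   `legend`.
#' @param legend named character vector mapping label value (name of the
#'   element, e.g. `"0"`) to class name. Label 0 is the background class.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels, legend) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(names(legend))) stop("legend must be a named character vector")
  used <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.character(used), names(legend))
  if (length(missing) > 0L) {
    stop(sprintf("labels without a legend entry: %s",
                 paste(missing, collapse = ", ")))
  }
  structure(list(labels = labels, legend = legend), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d pixels, %d legend entries\n",
              nrow(x$labels), ncol(x$labels), length(x$legend)))
  invisible(x)
}
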