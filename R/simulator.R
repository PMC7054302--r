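# Synthetic Macbeth-chart hypercube simulator.
#
# Emulates what the line-scanning hyperspectral endoscope records from a
# 24-square color calibration chart (18 painted colors + 6 grayscale squares):
# per-pixel reflectance spectra under a smooth halogen-like illuminant, sensor
# counts with white/dark calibration frames, Gaussian read noise, isolated
# fiber-cladding impulse artifacts, linear illumination bias/slope
# augmentation, and a tube (lumen) geometry with variable working distance.
# Ground-truth label maps are known exactly, so every downstream classifier
# can be scored without instrument data.

#' Chart layout specification
#'
#' The chart is a 4 x 6 grid of squares: rows 1-3 hold the 18 color classes
#' (class id `(row - 1) * 6 + col`), row 4 holds the 6 grayscale squares.
#' Training sections are the six 2 x 2 square blocks tiling the grid
#' (section 1..3 across the top half, 4..6 across the bottom half); sections
#' in the bottom half contain two grayscale squares, which carry the
#' background label. Squares are separated by dark margins, as on the
#' physical chart.
#'
#' @param margin_frac width of the dark margin around each square, as a
#'   fraction of the square edge (default 0.04).
#' @param gray_levels reflectances of the six grayscale squares.
#' @param margin_reflectance flat reflectance of the black separators.
#' @return object of class `chart_spec`.
#' @export
chart_spec <- function(margin_frac = 0.04,
                       gray_levels = c(0.03, 0.09, 0.19, 0.36, 0.59, 0.90),
                       margin_reflectance = 0.02) {
  stopifnot(margin_frac >= 0, margin_frac < 0.5, length(gray_levels) == 6L)
  structure(
    list(
      rows = 4L, cols = 6L, n_color_classes = 18L, n_gray = 6L,
      margin_frac = margin_frac, gray_levels = gray_levels,
      margin_reflectance = margin_reflectance
    ),
    class = "chart_spec"
  )
}

# squares of section s (1..6): a 2x2 block of the 4x6 grid
.section_squares <- function(section) {
  stopifnot(length(section) == 1L, section >= 1, section <= 6)
  srow <- if (section <= 3L) 1L else 2L
  scol <- as.integer((section - 1L) %% 3L) + 1L
  expand.grid(row = (2L * srow - 1L):(2L * srow),
              col = (2L * scol - 1L):(2L * scol))
}

# class id of a chart square; 0 = grayscale (background label)
.square_class <- function(row, col) {
  ifelse(row <= 3L, (row - 1L) * 6L + col, 0L)
}

#' Scene geometry for rendering
#'
#' Planar mode images the chart flat at constant working distance. Tube mode
#' bends the chart into a cylindrical lumen: working distance grows
#' quadratically from the line center toward the line edges, light collection
#' falls off as the inverse square of distance, and square boundaries blur
#' with a Gaussian kernel whose width grows with distance (colors blending
#' together toward the edges).
#'
#' @param mode `"planar"` or `"tube"`.
#' @param incidence_angle imaging angle in degrees (70-90); recorded in
#'   metadata, 90 = normal incidence.
#' @param distance_factor_max tube mode: working distance at the line edge
#'   relative to the line center (>= 1).
#' @param blur_sigma_max tube mode: Gaussian blur sigma (pixels along the
#'   line) at the farthest point; blur is 0 at the nearest point.
#' @param ny number of line pixels the working-distance profile is tabulated
#'   on (set at render time if `NULL`).
#' @return object of class `scene_geometry`.
#' @export
scene_geometry <- function(mode = c("planar", "tube"), incidence_angle = 90,
                           distance_factor_max = 1.25, blur_sigma_max = 1.5,
                           ny = NULL) {
  mode <- match.arg(mode)
  stopifnot(incidence_angle >= 70, incidence_angle <= 90,
            distance_factor_max >= 1, blur_sigma_max >= 0)
  structure(
    list(mode = mode, incidence_angle = incidence_angle,
         distance_factor_max = distance_factor_max,
         blur_sigma_max = blur_sigma_max, ny = ny),
    class = "scene_geometry"
  )
}

#' Per-line-pixel working distance profile
#'
#' @param geometry a [scene_geometry()].
#' @param ny number of line pixels.
#' @return numeric vector of relative working distances (1 at the nearest
#'   point).
#' @export
working_distance_profile <- function(geometry, ny) {
  u <- if (ny == 1L) 0 else (seq_len(ny) - 1) / (ny - 1)
  if (geometry$mode == "planar") {
    rep(1, ny)
  } else {
    1 + (geometry$distance_factor_max - 1) * (2 * u - 1)^2
  }
}

#' Synthesize a reference spectrum library
#'
#' The chart manufacturer's reflectance spectra are not distributed with the
#' package; this generates a stand-in library of 18 smooth, distinct
#' reflectance spectra on a 400-750 nm grid matching the halogen
#' illumination span, with display RGB codes derived from each spectrum.
#' Each class carries a signature reflectance band at a class-specific
#' wavelength (the bands tile the illumination window) plus one or two
#' randomly placed secondary bands over a low baseline — mimicking how
#' pigmented chart paints have distinctive band structure rather than being
#' expressible as mixtures of one another. Deterministic given `seed`.
#'
#' @param seed integer RNG seed.
#' @param wavelengths wavelength grid (nm).
#' @return a [reference_library()]; pairwise Pearson correlation between
#'   distinct class spectra is below 0.99.
#' @export
make_reference_library <- function(seed = 1L,
                                   wavelengths = seq(400, 750, by = 1)) {
  nl <- length(wavelengths)
  names18 <- c(
    "dark skin", "light skin", "blue sky", "foliage", "blue flower",
    "bluish green", "orange", "purplish blue", "moderate red", "purple",
    "yellow green", "orange yellow", "blue", "green", "red", "yellow",
    "magenta", "cyan"
  )
  span <- max(wavelengths) - min(wavelengths)
  draw_spectrum <- function(i) {
    base <- stats::runif(1L, 0.02, 0.12)
    s <- rep(base, nl)
    # signature band: class-specific center tiling the window, narrow width
    center <- min(wavelengths) + (i - 0.5) / 18 * span +
      stats::runif(1L, -6, 6)
    width <- stats::runif(1L, 18, 32)
    amp <- stats::runif(1L, 0.5, 0.85)
    s <- s + amp * exp(-0.5 * ((wavelengths - center) / width)^2)
    # secondary structure anywhere in the window
    for (j in seq_len(sample(1:2, 1L))) {
      c2 <- stats::runif(1L, 410, 740)
      w2 <- stats::runif(1L, 25, 70)
      a2 <- stats::runif(1L, 0.08, 0.30)
      s <- s + a2 * exp(-0.5 * ((wavelengths - c2) / w2)^2)
    }
    pmin(pmax(s, 0.01), 0.98)
  }
  with_seed(seed, {
    spectra <- t(vapply(1:18, draw_spectrum, numeric(nl)))
    rgb <- .spectrum_rgb(spectra, wavelengths)
    reference_library(names18, spectra, rgb, wavelengths)
  })
}

# display color from a reflectance spectrum: integrate against three broad
# Gaussian sensitivity curves (not colorimetric CIE matching, just a stable
# distinct display code per class)
.spectrum_rgb <- function(spectra, wavelengths) {
  sens <- cbind(
    exp(-0.5 * ((wavelengths - 610) / 45)^2),
    exp(-0.5 * ((wavelengths - 540) / 40)^2),
    exp(-0.5 * ((wavelengths - 465) / 35)^2)
  )
  sens <- sweep(sens, 2L, colSums(sens), "/")
  rgb <- as.matrix(spectra) %*% sens
  rgb <- rgb / max(rgb)
  pmin(pmax(rgb^0.8, 0), 1)  # mild gamma for display separation
}

# smooth halogen-like illuminant on the grid, peak-normalized (3200 K
# blackbody shape over the visible window)
.illuminant <- function(wavelengths) {
  l <- wavelengths * 1e-9
  b <- 1 / (l^5 * (exp(1.4388e-2 / (l * 3200)) - 1))
  b / max(b)
}

# per-pixel square index grid for one section; returns list(square, labels)
# square: integer matrix (nx, ny) with 0 = margin, 1..4 = section square
# labels: class labels (0 background for margins and grayscale squares)
.section_layout <- function(chart, section, nx, ny) {
  sq <- .section_squares(section)
  cls <- .square_class(sq$row, sq$col)
  # squares tile 2 along x (section rows) and 2 along y (section cols)
  assign_axis <- function(n) {
    # returns per-pixel square slot (0 margin, 1..2) along one axis
    half <- n / 2
    pos <- (seq_len(n) - 0.5) / half        # in (0, 2)
    slot <- pmin(floor(pos) + 1L, 2L)
    frac <- pos - (slot - 1L)               # position within square, (0,1)
    m <- chart$margin_frac
    inside <- frac > m & frac < (1 - m)
    ifelse(inside, slot, 0L)
  }
  ax <- assign_axis(nx)   # chart rows map to scan steps
  ay <- assign_axis(ny)   # chart cols map to line pixels
  square <- matrix(0L, nx, ny)
  labels <- matrix(0L, nx, ny)
  for (i in 1:2) for (j in 1:2) {
    # section square (i, j): row offset i, col offset j -> index into sq
    k <- which(sq$row == min(sq$row) + i - 1L & sq$col == min(sq$col) + j - 1L)
    mask <- outer(ax == i, ay == j, FUN = "&")
    square[mask] <- k
    labels[mask] <- cls[k]
  }
  gray_of <- function(k) {
    # grayscale square -> which gray level (by chart column)
    ifelse(cls[k] == 0L, sq$col[k], NA_integer_)
  }
  list(square = square, labels = labels, classes = cls,
       gray_index = vapply(1:4, gray_of, integer(1L)))
}

# banded sparse matrix applying a position-dependent Gaussian blur along y
.blur_operator <- function(sigma, ny) {
  halfw <- max(1L, ceiling(3 * max(sigma)))
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (y in seq_len(ny)) {
    if (sigma[y] < 1e-8) {
      rows <- c(rows, y); cols <- c(cols, y); vals <- c(vals, 1)
      next
    }
    idx <- max(1L, y - halfw):min(ny, y + halfw)
    w <- exp(-0.5 * ((idx - y) / sigma[y])^2)
    w <- w / sum(w)
    rows <- c(rows, rep(y, length(idx))); cols <- c(cols, idx)
    vals <- c(vals, w)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(ny, ny))
}

#' Render one chart section as a raw-count hypercube
#'
#' Produces what the camera would record from one 2 x 2-square section of the
#' chart: per-pixel reflectance spectra (from the library, grayscale levels
#' and dark margins), multiplied by a smooth halogen illuminant and the
#' geometry's working-distance attenuation, scaled to sensor counts between
#' the dark offset and the white level, plus Gaussian read noise and isolated
#' full-spectrum "salt and pepper" impulse pixels mimicking fiber-cladding
#' artifacts. Matching white/dark calibration frames and the exact label map
#' are returned alongside.
#'
#' @param chart a [chart_spec()].
#' @param section section index 1..6.
#' @param library a [reference_library()].
#' @param geometry a [scene_geometry()].
#' @param seed integer RNG seed.
#' @param nx,ny,nl cube dimensions (scan steps, line pixels, spectral
#'   channels); defaults (50, 512, 1209) match a full-resolution section
#'   acquisition.
#' @param noise_sd Gaussian read-noise standard deviation as a fraction of
#'   the white-minus-dark dynamic range.
#' @param artifact_frac fraction of spatial pixels replaced by impulse
#'   artifacts.
#' @param white_counts,dark_counts sensor count levels of the white reference
#'   and dark offset.
#' @return list with elements `cube` ([hypercube()] of counts), `cal`
#'   ([calibration_frames()]), `labels` ([label_map()]), and a `geometry_log`
#'   (working-distance, attenuation and blur-sigma profiles).
#' @export
render_base_hypercube <- function(chart, section, library, geometry,
                                  seed = 1L, nx = 50L, ny = 512L, nl = 1209L,
                                  noise_sd = 0.01, artifact_frac = 0.01,
                                  white_counts = 50000, dark_counts = 500) {
  stopifnot(inherits(chart, "chart_spec"),
            inherits(library, "reference_library"),
            inherits(geometry, "scene_geometry"))
  if (section < 1 || section > 6) stop("section must be in 1..6")
  wavelengths <- seq(400, 750, length.out = nl)
  lib <- resample_library(library, wavelengths)
  layout <- .section_layout(chart, section, nx, ny)
  illum <- .illuminant(wavelengths)
  dist <- working_distance_profile(geometry, ny)
  atten <- (1 / dist)^2
  atten <- atten / max(atten)
  sigma <- geometry$blur_sigma_max *
    (dist - min(dist)) / max(dist - min(dist), 1e-12)
  if (geometry$mode == "planar") sigma <- rep(0, ny)

  # reflectance spectrum of each section square (1..4) and of the margins
  sq_spec <- matrix(0, 5L, nl)            # row 5 = margin
  for (k in 1:4) {
    cl <- layout$classes[k]
    sq_spec[k, ] <- if (cl > 0L) lib$spectra[cl, ] else
      rep(chart$gray_levels[layout$gray_index[k]], nl)
  }
  sq_spec[5L, ] <- rep(chart$margin_reflectance, nl)

  # distinct x rows share their (y, lambda) reflectance image: build each
  # distinct row profile once, blur along y, then fill the cube
  row_key <- apply(layout$square, 1L, paste, collapse = ",")
  blur_op <- if (max(sigma) > 0) .blur_operator(sigma, ny) else NULL
  profile_cache <- new.env(parent = emptyenv())
  row_image <- function(x) {
    key <- row_key[x]
    if (!is.null(profile_cache[[key]])) return(profile_cache[[key]])
    sq_row <- layout$square[x, ]
    sq_row[sq_row == 0L] <- 5L
    img <- sq_spec[sq_row, , drop = FALSE]   # ny x nl reflectance
    if (!is.null(blur_op)) img <- as.matrix(blur_op %*% img)
    img <- img * atten                       # recycle along columns: (ny x nl)
    img <- dark_counts + img * illum_field * gain   # to sensor counts
    profile_cache[[key]] <- img
    img
  }

  gain <- white_counts - dark_counts
  illum_field <- outer(rep(1, ny), illum)                  # ny x nl
  white <- dark_counts + illum_field * gain
  dark <- matrix(dark_counts, ny, nl)

  with_seed(seed, {
    counts <- array(0, dim = c(nx, ny, nl))
    for (x in seq_len(nx)) {
      counts[x, , ] <- row_image(x)
    }
    if (noise_sd > 0) {
      counts <- counts + stats::rnorm(length(counts), sd = noise_sd * gain)
    }
    n_bad <- round(artifact_frac * nx * ny)
    bad <- if (n_bad > 0) sample(nx * ny, n_bad) else integer(0)
    if (n_bad > 0) {
      bx <- (bad - 1L) %% nx + 1L
      by <- (bad - 1L) %/% nx + 1L
      salt <- stats::runif(n_bad) < 0.5
      for (i in seq_len(n_bad)) {
        counts[bx[i], by[i], ] <- if (salt[i]) 1.3 * white_counts else 0
      }
    }
    counts <- pmin(pmax(counts, 0), 65535)
    legend <- stats::setNames(
      c("background", library$names),
      as.character(0:length(library$names))
    )
    list(
      cube = hypercube(counts, wavelengths,
                       meta = list(section = section, mode = geometry$mode,
                                   incidence_angle = geometry$incidence_angle)),
      cal = calibration_frames(white, dark),
      labels = label_map(layout$labels, legend),
      geometry_log = list(working_distance = dist, attenuation = atten,
                          blur_sigma = sigma)
    )
  })
}

#' Augmentation parameter set
#'
#' Augmented cubes are a base cube times a linear illumination field
#' `1 + sign * (b + s * u)` along the normalized line coordinate `u` in
#' \[0, 1\], plus additive Gaussian noise. The bias magnitude `b` is drawn
#' from Normal(`bias_mean`, `bias_sd`) and the slope `s` from
#' Normal(`slope_mean`, `slope_sd`); `sign` is -1 (under-illumination) with
#' probability `under_illumination_prob`, reflecting that endoscopy scenes
#' are more often under- than over-lit.
#'
#' @param bias_mean,bias_sd moments of the bias distribution (defaults 0.1,
#'   0.04).
#' @param slope_mean,slope_sd moments of the slope distribution (defaults
#'   0.01, 0.03).
#' @param noise_sd additive Gaussian noise scale, as a fraction of the base
#'   cube's dynamic range.
#' @param n_augmented number of augmented cubes to draw.
#' @param under_illumination_prob probability of the darkening sign.
#' @param seed integer RNG seed.
#' @return object of class `augmentation_params`.
#' @export
augmentation_params <- function(bias_mean = 0.1, bias_sd = 0.04,
                                slope_mean = 0.01, slope_sd = 0.03,
                                noise_sd = 0.02, n_augmented = 300L,
                                under_illumination_prob = 0.7, seed = 1L) {
  if (n_augmented < 0) stop("n_augmented must be >= 0")
  stopifnot(bias_sd >= 0, slope_sd >= 0, noise_sd >= 0,
            under_illumination_prob >= 0, under_illumination_prob <= 1)
  structure(
    list(bias_mean = bias_mean, bias_sd = bias_sd, slope_mean = slope_mean,
         slope_sd = slope_sd, noise_sd = noise_sd,
         n_augmented = as.integer(n_augmented),
         under_illumination_prob = under_illumination_prob,
         seed = as.integer(seed)),
    class = "augmentation_params"
  )
}

# apply one augmentation draw to a cube (field along the y axis)
.augment_one <- function(cube, bias, slope, sgn, noise_scale) {
  d <- dim(cube$data)
  u <- if (d[2L] == 1L) 0 else (seq_len(d[2L]) - 1) / (d[2L] - 1)
  field <- 1 + sgn * (bias + slope * u)
  data <- cube$data * rep(field, each = d[1L])   # broadcast over x, then lambda
  if (noise_scale > 0) {
    data <- data + stats::rnorm(length(data), sd = noise_scale)
  }
  hypercube(pmax(data, 0), cube$wavelengths, cube$meta)
}

#' Augment a pool of base hypercubes
#'
#' Draws `n_augmented` augmented cubes, each from a randomly chosen base
#' cube with a fresh linear illumination field and additive Gaussian noise
#' (see [augmentation_params()]). All draws are logged in the returned
#' manifest so their empirical moments can be recovered.
#'
#' @param base non-empty list of [hypercube()] objects (raw counts).
#' @param params an [augmentation_params()].
#' @return list of `n_augmented` hypercubes, with attribute `"manifest"`: a
#'   data frame with columns `index`, `base`, `bias`, `slope`, `sign`.
#' @export
augment <- function(base, params) {
  stopifnot(inherits(params, "augmentation_params"))
  if (length(base) == 0L) stop("base cube list must be non-empty")
  n <- params$n_augmented
  with_seed(params$seed, {
    base_idx <- if (n > 0) sample.int(length(base), n, replace = TRUE) else integer(0)
    bias <- stats::rnorm(n, params$bias_mean, params$bias_sd)
    slope <- stats::rnorm(n, params$slope_mean, params$slope_sd)
    sgn <- ifelse(stats::runif(n) < params$under_illumination_prob, -1, 1)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      b <- base[[base_idx[i]]]
      noise_scale <- params$noise_sd * diff(range(b$data))
      out[[i]] <- .augment_one(b, bias[i], slope[i], sgn[i], noise_scale)
    }
    attr(out, "manifest") <- data.frame(
      index = seq_len(n), base = base_idx, bias = bias, slope = slope,
      sign = sgn
    )
    out
  })
}

#' Draw an augmentation manifest without materializing cubes
#'
#' Reproduces exactly the draws [augment()] would log for the same `params`
#' and number of base cubes, without allocating the augmented cubes. Useful
#' for moment checks on the augmentation distributions and for streaming
#' pipelines that apply draws one cube at a time.
#'
#' @param n_base number of base cubes in the pool.
#' @param params an [augmentation_params()].
#' @return the manifest data frame (columns `index`, `base`, `bias`, `slope`,
#'   `sign`).
#' @export
augmentation_manifest <- function(n_base, params) {
  stopifnot(inherits(params, "augmentation_params"), n_base >= 1)
  n <- params$n_augmented
  with_seed(params$seed, {
    base_idx <- if (n > 0) sample.int(n_base, n, replace = TRUE) else integer(0)
    bias <- stats::rnorm(n, params$bias_mean, params$bias_sd)
    slope <- stats::rnorm(n, params$slope_mean, params$slope_sd)
    sgn <- ifelse(stats::runif(n) < params$under_illumination_prob, -1, 1)
    data.frame(index = seq_len(n), base = base_idx, bias = bias,
               slope = slope, sign = sgn)
  })
}

#' Render all six sections in tube (lumen) geometry
#'
#' The chart is bent into a cylindrical lumen: working distance increases
#' toward the line edges, intensity falls off with the inverse square of
#' distance, and square boundaries blur with a distance-dependent kernel.
#' Ground-truth labels are unchanged by attenuation and blur.
#'
#' @param chart a [chart_spec()].
#' @param library a [reference_library()].
#' @param seed integer RNG seed (each section gets a derived sub-seed).
#' @param geometry a tube-mode [scene_geometry()]; pass a planar geometry to
#'   recover the planar rendering exactly.
#' @param sections which sections to render (default all six).
#' @param ... further arguments to [render_base_hypercube()] (`nx`, `ny`,
#'   `nl`, `noise_sd`, ...).
#' @return list with `sections` (one [render_base_hypercube()] result per
#'   requested section) and `geometry`.
#' @export
render_tube_dataset <- function(chart, library, seed = 1L,
                                geometry = scene_geometry("tube"),
                                sections = 1:6, ...) {
  out <- lapply(seq_along(sections), function(i) {
    render_base_hypercube(chart, sections[i], library, geometry,
                          seed = seed + 1000L * i, ...)
  })
  list(sections = out, geometry = geometry)
}
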