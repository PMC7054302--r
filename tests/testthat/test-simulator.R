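test_that("reference library synthesis is deterministic and in range", {
  l1 <- tiny_library(seed = 7)
  l2 <- tiny_library(seed = 7)
  expect_identical(l1$spectra, l2$spectra)
  expect_identical(l1$rgb, l2$rgb)
  expect_gte(min(l1$spectra), 0)
  expect_lte(max(l1$spectra), 1)
  expect_length(l1$names, 18L)
  expect_identical(l1$background_label, 0L)
})

test_that("library correlation matrix has unit diagonal and distinct classes", {
  for (seed in c(1, 7, 23)) {
    lib <- tiny_library(seed = seed)
    cm <- stats::cor(t(lib$spectra))
    expect_equal(unname(diag(cm)), rep(1, 18))
    expect_lt(max(cm - diag(18)), 0.99)
  }
})

test_that("rendered cube has the requested shape and calibration frames", {
  r <- tiny_render(nx = 6L, ny = 40L, nl = 150L)
  expect_identical(dim(r$cube), c(6L, 40L, 150L))
  expect_identical(dim(r$cal$white), c(40L, 150L))
  expect_true(all(r$cal$white > r$cal$dark))
  expect_identical(dim(r$labels$labels), c(6L, 40L))
  expect_error(tiny_render(section = 7L), "section")
})

test_that("noiseless planar pixels equal their class spectrum after normalization", {
  r <- tiny_render(nx = 6L, ny = 48L, nl = 242L, noise_sd = 0,
                   artifact_frac = 0)
  norm <- normalize_reflectance(r$cube, r$cal)
  lib <- resample_library(tiny_library(), r$cube$wavelengths)
  lab <- r$labels$labels
  for (cl in setdiff(unique(as.vector(lab)), 0L)) {
    px <- which(lab == cl, arr.ind = TRUE)[1, ]
    expect_equal(norm$data[px[1], px[2], ], unname(lib$spectra[cl, ]),
                 tolerance = 1e-12)
  }
})

test_that("label map square boundaries match an independently coded layout", {
  chart <- chart_spec()
  nx <- 10L; ny <- 64L
  r <- tiny_render(section = 2L, nx = nx, ny = ny)
  # independent oracle: recompute the 2x2 block layout from first principles
  sq <- expand.grid(row = 1:2, col = 3:4)   # section 2 squares
  cls <- ifelse(sq$row <= 3, (sq$row - 1) * 6 + sq$col, 0L)
  axis_slot <- function(n) {
    pos <- (seq_len(n) - 0.5) / (n / 2)
    slot <- pmin(floor(pos) + 1, 2)
    frac <- pos - (slot - 1)
    ifelse(frac > chart$margin_frac & frac < 1 - chart$margin_frac, slot, 0)
  }
  ax <- axis_slot(nx); ay <- axis_slot(ny)
  expected <- matrix(0L, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (ax[i] > 0 && ay[j] > 0) {
      k <- which(sq$row == ax[i] & sq$col == 2 + ay[j])
      expected[i, j] <- as.integer(cls[k])
    }
  }
  expect_identical(r$labels$labels, expected)
})

test_that("grayscale squares carry the background label", {
  # sections 4-6 cover the bottom chart half, containing the gray row
  r <- tiny_render(section = 5L, nx = 10L, ny = 64L)
  lab <- r$labels$labels
  # bottom square row (x slots in the second half) is grayscale: label 0
  expect_true(all(lab[8:10, ] == 0L))
  expect_true(any(lab[2:4, ] > 0L))
})

test_that("rendering is deterministic given the seed", {
  r1 <- tiny_render(seed = 11)
  r2 <- tiny_render(seed = 11)
  expect_identical(r1$cube$data, r2$cube$data)
  r3 <- tiny_render(seed = 12)
  expect_false(identical(r1$cube$data, r3$cube$data))
})

test_that("augment returns the requested pool and logs every draw", {
  base <- lapply(1:3, function(s)
    tiny_render(section = s, nx = 3L, ny = 16L, nl = 121L)$cube)
  params <- augmentation_params(n_augmented = 25L, seed = 5L)
  out <- augment(base, params)
  expect_length(out, 25L)
  man <- attr(out, "manifest")
  expect_identical(nrow(man), 25L)
  expect_true(all(man$base %in% 1:3))
  expect_true(all(man$sign %in% c(-1, 1)))
  expect_error(augmentation_params(n_augmented = -1), "n_augmented")
  expect_error(augment(list(), params), "non-empty")
})

test_that("degenerate augmentation applies exactly the constant field", {
  base <- list(tiny_render(nx = 3L, ny = 17L, nl = 121L, noise_sd = 0,
                           artifact_frac = 0)$cube)
  params <- augmentation_params(bias_sd = 0, slope_sd = 0, noise_sd = 0,
                                n_augmented = 4L, seed = 9L)
  out <- augment(base, params)
  u <- (seq_len(17) - 1) / 16
  for (cube in out) {
    ratio <- cube$data / base[[1]]$data
    # |field - 1| = bias_mean + slope_mean * u regardless of the drawn sign
    dev <- abs(ratio - 1)
    expected <- matrix(rep(0.1 + 0.01 * u, each = 3), 3, 17)
    for (k in c(1, 60, 121)) {
      expect_equal(dev[, , k], expected, tolerance = 1e-10)
    }
  }
})

test_that("augmentation draw moments recover the configured distributions", {
  params <- augmentation_params(n_augmented = 400L, seed = 2L)
  man <- augmentation_manifest(12L, params)
  n <- nrow(man)
  # within 4 standard errors of the configured moments
  expect_lt(abs(mean(man$bias) - 0.1), 4 * 0.04 / sqrt(n))
  expect_lt(abs(mean(man$slope) - 0.01), 4 * 0.03 / sqrt(n))
  expect_lt(abs(stats::sd(man$bias) - 0.04), 4 * 0.04 / sqrt(2 * n))
  expect_lt(abs(stats::sd(man$slope) - 0.03), 4 * 0.03 / sqrt(2 * n))
  # under-illumination is the more probable sign
  expect_gt(mean(man$sign == -1), 0.5)
})

test_that("augmentation manifest matches the draws augment() logs", {
  base <- lapply(1:2, function(s)
    tiny_render(section = s, nx = 2L, ny = 8L, nl = 121L)$cube)
  params <- augmentation_params(n_augmented = 10L, seed = 13L)
  expect_identical(attr(augment(base, params), "manifest"),
                   augmentation_manifest(2L, params))
})

test_that("tube rendering with attenuation and blur disabled equals planar", {
  planar <- tiny_render(seed = 4, geometry = scene_geometry("planar"))
  flat_tube <- tiny_render(seed = 4, geometry = scene_geometry(
    "tube", distance_factor_max = 1, blur_sigma_max = 0))
  expect_equal(planar$cube$data, flat_tube$cube$data, tolerance = 1e-12)
})

test_that("tube attenuation darkens the far (edge) line regions", {
  r <- tiny_render(seed = 4, nx = 6L, ny = 64L,
                   geometry = scene_geometry("tube",
                                             distance_factor_max = 1.4))
  cube <- r$cube$data
  near <- mean(cube[, 29:36, ])   # line center = nearest working distance
  far <- mean(cube[, c(1:4, 61:64), ])
  expect_gt(near, far)
  # ground truth unchanged by attenuation
  planar <- tiny_render(seed = 4, nx = 6L, ny = 64L)
  expect_identical(r$labels$labels, planar$labels$labels)
})

test_that("logged blur schedule reaches the configured maximum at the far point", {
  g <- scene_geometry("tube", blur_sigma_max = 2.5)
  r <- tiny_render(seed = 1, geometry = g, nx = 4L, ny = 32L)
  log <- r$geometry_log
  expect_equal(max(log$blur_sigma), 2.5)
  expect_equal(log$blur_sigma[which.max(log$working_distance)], 2.5)
  expect_equal(min(log$blur_sigma), 0)
  # working distance grows monotonically from the line center outward
  expect_true(all(diff(log$working_distance[1:16]) <= 0))
  expect_true(all(diff(log$working_distance[17:32]) >= 0))
})

test_that("noiseless simulation is perfectly separable by nearest reference", {
  r <- tiny_render(nx = 6L, ny = 48L, nl = 242L, noise_sd = 0,
                   artifact_frac = 0)
  pp <- preprocess_cube(r$cube, r$cal, n_bins = 121L)
  model <- pearson_model(tiny_library())
  pred <- predict_spectra(model, pp$binned)$labels
  lab <- as.vector(r$labels$labels)
  colored <- lab > 0
  expect_equal(mean(pred[colored] == lab[colored]), 1)
})
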