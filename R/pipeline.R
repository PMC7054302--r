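# End-to-end dataset assembly: base sections -> augmentation -> preprocessed
# pixel pool, the protocol used for training and benchmarking the
# classifiers on synthetic chart data.

#' Simulate a preprocessed training pool
#'
#' Renders the six chart sections in `n_replicates` replicates (the base
#' cubes), draws `n_augmented` augmented cubes (linear illumination fields
#' plus Gaussian noise), and preprocesses every cube (normalize, median
#' filter, bin) into a per-pixel pool ready for classifier training. Cubes
#' are processed one at a time so the raw pool is never held in memory.
#'
#' @param chart a [chart_spec()].
#' @param library a [reference_library()].
#' @param geometry a [scene_geometry()].
#' @param n_replicates replicate measurements per section (default 2: 6
#'   sections x 2 = 12 base cubes).
#' @param params an [augmentation_params()] (its `n_augmented` and `seed`
#'   drive the augmentation draws).
#' @param sections sections to render (default all six; a single section
#'   gives the four-color protocol).
#' @param seed integer RNG seed for the base renders.
#' @param nx,ny,nl cube dimensions.
#' @param n_bins spectral bins after preprocessing (default 121).
#' @param ... further arguments to [render_base_hypercube()].
#' @return list with `entries` (one per cube:
#'   `list(binned, labels, base_id, augmented)`), `manifest` (the
#'   augmentation draw log) and `legend`.
#' @export
simulate_training_pool <- function(chart, library, geometry,
                                   n_replicates = 2L,
                                   params = augmentation_params(),
                                   sections = 1:6, seed = 1L,
                                   nx = 50L, ny = 512L, nl = 1209L,
                                   n_bins = 121L, ...) {
  base_raw <- list()
  base_meta <- list()
  id <- 0L
  for (rep_i in seq_len(n_replicates)) {
    for (s in sections) {
      id <- id + 1L
      r <- render_base_hypercube(chart, s, library, geometry,
                                 seed = seed + 101L * id,
                                 nx = nx, ny = ny, nl = nl, ...)
      base_raw[[id]] <- r
      base_meta[[id]] <- list(section = s, replicate = rep_i)
    }
  }
  legend <- base_raw[[1L]]$labels$legend
  manifest <- augmentation_manifest(length(base_raw), params)

  prep <- function(cube, cal) {
    preprocess_cube(cube, cal, n_bins = n_bins)$binned
  }
  entries <- vector("list", length(base_raw) + nrow(manifest))
  for (i in seq_along(base_raw)) {
    r <- base_raw[[i]]
    entries[[i]] <- list(
      binned = prep(r$cube, r$cal),
      labels = as.vector(r$labels$labels),
      base_id = i, augmented = FALSE,
      section = base_meta[[i]]$section
    )
  }
  if (nrow(manifest) > 0L) {
    # reproduce augment()'s per-cube noise draws one cube at a time
    noise_seeds <- with_seed(params$seed + 1L,
                             sample.int(.Machine$integer.max, nrow(manifest)))
    for (j in seq_len(nrow(manifest))) {
      b <- manifest$base[j]
      r <- base_raw[[b]]
      noise_scale <- params$noise_sd * diff(range(r$cube$data))
      aug <- with_seed(noise_seeds[j],
                       .augment_one(r$cube, manifest$bias[j],
                                    manifest$slope[j], manifest$sign[j],
                                    noise_scale))
      entries[[length(base_raw) + j]] <- list(
        binned = prep(aug, r$cal),
        labels = as.vector(r$labels$labels),
        base_id = b, augmented = TRUE,
        section = base_meta[[b]]$section
      )
    }
  }
  list(entries = entries, manifest = manifest, legend = legend)
}

#' Benchmark all classifier families on a common pool
#'
#' Trains the pixel-wise CNN, one-vs-one SVM, supervised and unsupervised
#' unmixing and Pearson matching on a shared train/validation split
#' (group-aware: augmented cubes stay with their base cube) and scores
#' ACC_av for each family on the same held-out pixels.
#'
#' @param pool result of [simulate_training_pool()].
#' @param library the [reference_library()] used to simulate the pool.
#' @param families which families to run.
#' @param arch pixel [cnn_architecture()].
#' @param config [training_config()] for the CNN.
#' @param holdout_fold which fold (of `k`) is held out.
#' @param k fold count for the group-aware split.
#' @param train_pixels_per_cube,eval_pixels_per_cube pixel subsampling.
#' @param unmix_eval_pixels at most this many held-out pixels are scored for
#'   the (slow) per-pixel NNLS family.
#' @param classes when the pool covers a subset of the chart (the four-color
#'   protocol), the class labels present: the library-matching families then
#'   match against that subset only, as the comparison protocol trains every
#'   method on the same restricted color set.
#' @param seed integer RNG seed.
#' @return list of `evaluation_report`s keyed by family, plus the split.
#' @export
benchmark_families <- function(pool, library,
                               families = c("cnn_pixel", "svm",
                                            "unmix_supervised",
                                            "unmix_unsupervised", "pearson"),
                               arch = cnn_architecture("pixel"),
                               config = training_config(),
                               holdout_fold = 1L, k = 5L,
                               train_pixels_per_cube = 200L,
                               eval_pixels_per_cube = 2000L,
                               unmix_eval_pixels = 3000L, classes = NULL,
                               seed = 1L) {
  entries <- pool$entries
  base_ids <- vapply(entries, function(e) e$base_id, integer(1L))
  folds <- cv_folds(base_ids, k = k, seed = seed)
  tr <- folds != holdout_fold
  va <- folds == holdout_fold

  sample_pixels <- function(entry, n_px, salt) {
    n <- length(entry$labels)
    idx <- if (is.finite(n_px) && n_px < n)
      with_seed(seed + salt, sample.int(n, n_px)) else seq_len(n)
    list(x = entry$binned[idx, , drop = FALSE], y = entry$labels[idx])
  }
  tr_parts <- lapply(which(tr), function(i)
    sample_pixels(entries[[i]], train_pixels_per_cube, i))
  Xtr <- do.call(rbind, lapply(tr_parts, `[[`, "x"))
  ytr <- unlist(lapply(tr_parts, `[[`, "y"))
  va_parts <- lapply(which(va), function(i)
    sample_pixels(entries[[i]], eval_pixels_per_cube, 7919L + i))
  Xva <- do.call(rbind, lapply(va_parts, `[[`, "x"))
  yva <- unlist(lapply(va_parts, `[[`, "y"))

  score <- function(pred, ref) {
    accuracy(matrix(as.integer(pred), nrow = 1L),
             matrix(as.integer(ref), nrow = 1L))
  }
  match_lib <- if (is.null(classes)) library else
    subset_library(library, classes)
  reports <- list()
  for (fam in families) {
    if (fam == "cnn_pixel") {
      model <- build_pixel_cnn(arch, seed = seed, library = library)
      model <- train_cnn(model, Xtr, ytr, config)
      pred <- max.col(.cnn_predict_matrix(model, .cnn_feature_matrix(Xva)),
                      ties.method = "first") - 1L
      reports[[fam]] <- score(pred, yva)
      reports[[fam]]$model <- model
    } else if (fam == "svm") {
      model <- svm_train(Xtr, ytr, library = library)
      pred <- predict_spectra(model, Xva)$labels
      reports[[fam]] <- score(pred, yva)
      reports[[fam]]$n_binary <- model$n_binary
    } else if (fam == "unmix_supervised") {
      model <- unmix_supervised_model(match_lib)
      n_eval <- min(unmix_eval_pixels, nrow(Xva))
      idx <- with_seed(seed + 31L, sample.int(nrow(Xva), n_eval))
      pred <- predict_spectra(model, Xva[idx, , drop = FALSE])$labels
      reports[[fam]] <- score(pred, yva[idx])
    } else if (fam == "unmix_unsupervised") {
      # one endmember per expected class plus one for background material
      k <- length(match_lib$names) + 1L
      fit <- predict_spectra(
        unmix_unsupervised_model(match_lib, k = k, seed = seed), Xva)
      reports[[fam]] <- score(fit$labels, yva)
    } else if (fam == "pearson") {
      model <- pearson_model(match_lib)
      pred <- predict_spectra(model, Xva)$labels
      reports[[fam]] <- score(pred, yva)
    } else stop(sprintf("unknown family '%s'", fam))
  }
  list(reports = reports, folds = folds, n_train = nrow(Xtr),
       n_eval = nrow(Xva))
}
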