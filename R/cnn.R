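# Pixel-wise and slice-wise convolutional classifiers.
#
# The pixel-wise network consumes one 11 x 11 spectral patch per spatial
# pixel (the wrapped 121-sample binned spectrum) and emits a 19-way softmax:
# 18 color classes plus the background class for spectra matching none of
# them. Two convolutional layers and two fully connected layers, ReLU
# throughout, 40% dropout and L2 weight decay, trained by mini-batch
# momentum SGD with early stopping on the validation misclassification rate
# (argmax of the prediction differing from argmax of the one-hot reference).
#
# The slice-wise variant consumes a whole (y, 121) binned spatial-spectral
# slice through four convolutional layers with max-pooling along the
# spectral axis and two fully connected layers applied per line pixel,
# producing a dense per-pixel label row.

#' CNN architecture description
#'
#' @param variant `"pixel"` (2 conv + 2 fully connected layers on 11 x 11
#'   patches) or `"slice"` (4 conv + 2 fully connected layers with
#'   max-pooling on whole `(y, 121)` slices).
#' @param conv_filters filter counts per convolutional layer (pixel default
#'   `c(32, 64)`, slice default `c(8, 16, 16, 32)`).
#' @param kernel square kernel edge (default 3).
#' @param fc_width width of the first fully connected layer (the second is
#'   the 19-way output).
#' @param dropout_rate dropout on the first fully connected layer (default
#'   0.40).
#' @param l2_coefficient L2 weight-decay coefficient (default 1e-4).
#' @param n_outputs number of softmax outputs (default 19: 18 colors +
#'   background).
#' @return object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(variant = c("pixel", "slice"),
                             conv_filters = NULL, kernel = 3L,
                             fc_width = NULL, dropout_rate = 0.40,
                             l2_coefficient = 1e-4, n_outputs = 19L) {
  variant <- match.arg(variant)
  if (is.null(conv_filters)) {
    conv_filters <- if (variant == "pixel") c(32L, 64L) else c(8L, 16L, 16L, 32L)
  }
  if (is.null(fc_width)) fc_width <- if (variant == "pixel") 128L else 64L
  n_conv <- length(conv_filters)
  if (variant == "pixel" && n_conv != 2L) {
    stop("the pixel-wise architecture has exactly 2 convolutional layers")
  }
  if (variant == "slice" && n_conv != 4L) {
    stop("the slice-wise architecture has exactly 4 convolutional layers")
  }
  stopifnot(dropout_rate >= 0, dropout_rate < 1, l2_coefficient >= 0,
            n_outputs >= 2)
  structure(
    list(variant = variant, conv_filters = as.integer(conv_filters),
         kernel = as.integer(kernel), fc_width = as.integer(fc_width),
         dropout_rate = dropout_rate, l2_coefficient = l2_coefficient,
         n_outputs = as.integer(n_outputs)),
    class = "cnn_architecture"
  )
}

#' Training configuration
#'
#' @param batch_size mini-batch size (default 100).
#' @param learning_rate SGD learning rate (default 0.001), momentum-adjusted.
#' @param momentum momentum coefficient (default 0.9).
#' @param max_epochs epoch cap (default 900).
#' @param patience early stopping: epochs without improvement of the
#'   validation misclassification rate before stopping (default 20).
#' @param min_delta minimum improvement counted by the patience rule.
#' @param validation_fraction share of the training set held out for the
#'   stopping metric when no explicit validation set is given.
#' @param seed integer RNG seed (initialization, shuffling, dropout).
#' @return object of class `training_config`.
#' @export
training_config <- function(batch_size = 100L, learning_rate = 0.001,
                            momentum = 0.9, max_epochs = 900L,
                            patience = 20L, min_delta = 0,
                            validation_fraction = 0.1, seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, learning_rate >= 0,
            momentum >= 0, momentum < 1, patience >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         momentum = momentum, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), min_delta = min_delta,
         validation_fraction = validation_fraction, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Build the pixel-wise patch CNN
#'
#' @param arch a pixel-variant [cnn_architecture()].
#' @param seed integer RNG seed for parameter initialization.
#' @param library optional [reference_library()] attached for label/display
#'   bookkeeping.
#' @return an untrained `hyse_model` of family `cnn_pixel`.
#' @export
build_pixel_cnn <- function(arch = cnn_architecture("pixel"), seed = 1L,
                            library = NULL) {
  stopifnot(inherits(arch, "cnn_architecture"))
  if (arch$variant != "pixel") stop("arch must be the pixel variant")
  k <- arch$kernel
  with_seed(seed, {
    p1 <- .conv_plan(11L, 11L, 1L, k, k, arch$conv_filters[1L])
    p2 <- .conv_plan(p1$OH, p1$OW, arch$conv_filters[1L], k, k,
                     arch$conv_filters[2L])
    n_flat <- p2$P * p2$nf
    layers <- list(
      .layer_conv(p1),
      .layer_conv(p2),
      .layer_dense(n_flat, arch$fc_width, "relu"),
      list(type = "dropout"),
      .layer_dense(arch$fc_width, arch$n_outputs, "linear")
    )
    structure(
      list(family = "cnn_pixel", arch = arch, library = library,
           net = list(layers = layers, vel = vector("list", length(layers)),
                      l2 = arch$l2_coefficient,
                      dropout_rate = arch$dropout_rate),
           trained = FALSE, seed = as.integer(seed)),
      class = c("hyse_cnn", "hyse_model")
    )
  })
}

#' Build the slice-wise CNN
#'
#' @param arch a slice-variant [cnn_architecture()].
#' @param ny number of line pixels per slice (input height).
#' @param n_bins spectral input width (default 121).
#' @param seed integer RNG seed.
#' @param library optional [reference_library()].
#' @return an untrained `hyse_model` of family `cnn_slice`; prediction emits
#'   one label per line pixel.
#' @export
build_slice_cnn <- function(arch = cnn_architecture("slice"), ny,
                            n_bins = 121L, seed = 1L, library = NULL) {
  stopifnot(inherits(arch, "cnn_architecture"))
  if (arch$variant != "slice") stop("arch must be the slice variant")
  k <- arch$kernel
  pad <- (k - 1L) %/% 2L
  with_seed(seed, {
    layers <- list()
    H <- as.integer(ny); W <- as.integer(n_bins); C <- 1L
    for (i in seq_along(arch$conv_filters)) {
      plan <- .conv_plan(H, W, C, k, k, arch$conv_filters[i], pad = pad)
      layers[[length(layers) + 1L]] <- .layer_conv(plan)
      H <- plan$OH; W <- plan$OW; C <- plan$nf
      pool <- .layer_pool_w(H, W, C)
      layers[[length(layers) + 1L]] <- pool
      W <- pool$OW
    }
    layers[[length(layers) + 1L]] <- list(type = "reshape_rows", H = H,
                                          F = W * C)
    layers[[length(layers) + 1L]] <- .layer_dense(W * C, arch$fc_width, "relu")
    layers[[length(layers) + 1L]] <- list(type = "dropout")
    layers[[length(layers) + 1L]] <- .layer_dense(arch$fc_width,
                                                  arch$n_outputs, "linear")
    structure(
      list(family = "cnn_slice", arch = arch, library = library,
           ny = as.integer(ny), n_bins = as.integer(n_bins),
           net = list(layers = layers, vel = vector("list", length(layers)),
                      l2 = arch$l2_coefficient,
                      dropout_rate = arch$dropout_rate),
           trained = FALSE, seed = as.integer(seed)),
      class = c("hyse_cnn", "hyse_model")
    )
  })
}

# accept patches (list), a (N x 121) matrix of binned spectra, or a 3-D
# (N, 11, 11) array; returns the engine's (N x 121) feature matrix
.cnn_feature_matrix <- function(x) {
  if (is.list(x)) {
    return(t(vapply(x, function(p) as.vector(unclass(p)), numeric(121L))))
  }
  if (is.matrix(x)) {
    if (ncol(x) != 121L) stop("binned spectra must have 121 columns")
    # rows are unwrapped spectra: permute into the patch's column-major
    # layout (as.vector(wrap_patch(v)) == v[perm])
    perm <- as.vector(matrix(1:121, 11L, 11L, byrow = TRUE))
    return(x[, perm, drop = FALSE])
  }
  stop("unsupported input for the pixel-wise CNN")
}

.one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Synthesize background-class training exemplars
#'
#' A softmax cannot emit a background label it was never trained on. Besides
#' the margin pixels present in labeled data, the background class is given
#' explicit exemplars of the spectra it must absorb: dark (near-zero)
#' pixels, fiber-cladding-like impulse spectra, and 50/50 mixtures of two
#' reference colors (boundary pixels belonging to no single class).
#'
#' @param library a [reference_library()].
#' @param n number of exemplars.
#' @param n_bins spectral length (default 121).
#' @param seed integer RNG seed.
#' @return `(n, n_bins)` matrix of binned spectra, all to be labeled 0.
#' @export
synthesize_background_spectra <- function(library, n, n_bins = 121L,
                                          seed = 1L) {
  refs <- .binned_refs(library, n_bins)
  with_seed(seed, {
    kind <- sample(c("dark", "mixture", "cladding"), n, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))
    out <- matrix(0, n, n_bins)
    for (i in seq_len(n)) {
      out[i, ] <- switch(kind[i],
        dark = pmax(stats::rnorm(n_bins, mean = stats::runif(1, 0, 0.03),
                                 sd = 0.005), 0),
        mixture = {
          pair <- sample(nrow(refs), 2L)
          0.5 * refs[pair[1L], ] + 0.5 * refs[pair[2L], ]
        },
        cladding = {
          s <- rep(stats::runif(1, 0, 0.1), n_bins)
          spikes <- sample(n_bins, sample(3:12, 1L))
          s[spikes] <- stats::runif(length(spikes), 0.8, 1)
          s
        })
    }
    out
  })
}

#' Train a CNN classifier
#'
#' Mini-batch momentum SGD on softmax cross-entropy with L2 weight decay and
#' dropout. After every epoch the misclassification rate (prediction argmax
#' differing from the one-hot reference argmax) is evaluated on the
#' validation set; training stops at `max_epochs` or once the rate has not
#' improved for `patience` epochs, restoring the best parameters.
#'
#' @param model an untrained `hyse_cnn` from [build_pixel_cnn()] or
#'   [build_slice_cnn()].
#' @param x training inputs: for the pixel variant a list of
#'   `spectral_patch`, an `(N, 121)` binned-spectra matrix or an
#'   `(N, 11, 11)` array; for the slice variant an `(N, ny, 121)` array of
#'   binned slices.
#' @param labels integer labels in `0..n_outputs-1` (0 = background): one per
#'   patch (pixel variant) or an `(N, ny)` matrix (slice variant).
#' @param config a [training_config()].
#' @param validation optional `list(x = ..., labels = ...)` held-out set; if
#'   absent, `validation_fraction` of the training data is held out.
#' @return the trained model, with a `log` data frame (epoch, training loss,
#'   validation error) and `epochs_run`/`best_val_error` fields.
#' @export
train_cnn <- function(model, x, labels, config = training_config(),
                      validation = NULL) {
  stopifnot(inherits(model, "hyse_cnn"), inherits(config, "training_config"))
  n_out <- model$arch$n_outputs
  if (model$family == "cnn_pixel") {
    X <- .cnn_feature_matrix(if (is.array(x) && length(dim(x)) == 3L)
      matrix(x, dim(x)[1L], 121L) else x)
    y <- as.integer(labels)
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3L)
    N <- dim(x)[1L]
    X <- x
    dim(X) <- c(N, dim(x)[2L] * dim(x)[3L])
    y <- as.matrix(labels)
  }
  if (any(unlist(labels) < 0L) || any(unlist(labels) >= n_out)) {
    stop(sprintf("labels must lie in 0..%d", n_out - 1L))
  }
  if (NROW(X) == 0L) stop("training set is empty")

  with_seed(config$seed, {
    n <- nrow(X)
    if (is.null(validation)) {
      n_val <- max(1L, round(config$validation_fraction * n))
      if (config$validation_fraction == 0) n_val <- 0L
      idx <- sample.int(n)
      val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
      tr_idx <- setdiff(idx, val_idx)
    } else {
      tr_idx <- seq_len(n)
      val_idx <- integer(0)
    }
    Xtr <- X[tr_idx, , drop = FALSE]
    ytr <- if (is.matrix(y)) y[tr_idx, , drop = FALSE] else y[tr_idx]
    if (length(val_idx) > 0L) {
      Xval <- X[val_idx, , drop = FALSE]
      yval <- if (is.matrix(y)) y[val_idx, , drop = FALSE] else y[val_idx]
    } else if (!is.null(validation)) {
      if (model$family == "cnn_pixel") {
        Xval <- .cnn_feature_matrix(validation$x)
        yval <- as.integer(validation$labels)
      } else {
        Xval <- validation$x
        dim(Xval) <- c(dim(validation$x)[1L],
                       dim(validation$x)[2L] * dim(validation$x)[3L])
        yval <- as.matrix(validation$labels)
      }
    } else {
      Xval <- NULL
    }

    net <- model$net
    n_tr <- nrow(Xtr)
    batches_per_epoch <- max(1L, ceiling(n_tr / config$batch_size))
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      val_error = numeric(0))
    best_err <- Inf
    best_net <- net
    stall <- 0L
    epochs_run <- 0L

    val_error <- function(net) {
      if (is.null(Xval)) return(NA_real_)
      pred <- .net_forward(net, Xval, train = FALSE)$probs
      pl <- max.col(pred, ties.method = "first") - 1L
      # slice variant: prediction rows are (b, h) with b fastest, matching
      # the column-major flattening of the (N, ny) label matrix
      ref <- if (is.matrix(yval)) as.vector(yval) else yval
      mean(pl != ref)
    }

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      epoch_loss <- 0
      for (bi in seq_len(batches_per_epoch)) {
        rows <- ord[(((bi - 1L) * config$batch_size + 1L):
                       min(bi * config$batch_size, n_tr))]
        Xb <- Xtr[rows, , drop = FALSE]
        yb <- if (is.matrix(ytr)) ytr[rows, , drop = FALSE] else ytr[rows]
        Yb <- if (is.matrix(yb)) .one_hot(as.vector(yb), n_out) else
          .one_hot(yb, n_out)
        fwd <- .net_forward(net, Xb, train = TRUE)
        epoch_loss <- epoch_loss + .net_loss(net, fwd$probs, Yb)
        grads <- .net_backward(net, fwd, Yb)
        net <- .net_sgd_step(net, grads, config$learning_rate,
                             config$momentum)
      }
      epochs_run <- epoch
      err <- val_error(net)
      log <- rbind(log, data.frame(epoch = epoch,
                                   loss = epoch_loss / batches_per_epoch,
                                   val_error = err))
      if (!is.na(err)) {
        if (err < best_err - config$min_delta) {
          best_err <- err
          best_net <- net
          stall <- 0L
        } else {
          # among epochs tied at the best rate, keep the most-trained model
          # (training loss keeps improving after the stopping metric floors)
          if (err <= best_err) best_net <- net
          stall <- stall + 1L
          if (stall >= config$patience) break
        }
      } else {
        best_net <- net
      }
    }

    model$net <- if (is.finite(best_err)) best_net else net
    model$trained <- TRUE
    model$log <- log
    model$epochs_run <- epochs_run
    model$best_val_error <- if (is.finite(best_err)) best_err else NA_real_
    model
  })
}

# forward pass labels/probabilities for a feature matrix
.cnn_predict_matrix <- function(model, X, batch = 4096L) {
  n <- nrow(X)
  probs <- matrix(0, n, model$arch$n_outputs)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    probs[i:j, ] <- .net_forward(model$net, X[i:j, , drop = FALSE],
                                 train = FALSE)$probs
    i <- j + 1L
  }
  probs
}

#' Classify one slice of spectral patches
#'
#' Per-pixel argmax over the 19-way softmax; the background class is an
#' ordinary trained output. Wall-clock classification time is recorded for
#' frames-per-second accounting.
#'
#' @param model a trained `hyse_model`.
#' @param patches list of `spectral_patch` (or an `(ny, 121)` binned matrix).
#' @param ... passed to the family's prediction routine.
#' @return a `classification_result`: `labels` (integer vector, 0 =
#'   background), `probabilities` (or scores), `per_slice_seconds`.
#' @export
classify_slice <- function(model, patches, ...) {
  stopifnot(inherits(model, "hyse_model"))
  if (inherits(model, "hyse_cnn") && !isTRUE(model$trained)) {
    stop("model has not been trained")
  }
  t0 <- proc.time()[["elapsed"]]
  if (inherits(model, "hyse_cnn") && model$family == "cnn_slice") {
    binned <- if (is.list(patches)) attr(patches, "binned") else patches
    stopifnot(is.matrix(binned))
    X <- matrix(binned, 1L, length(binned))
    probs <- .net_forward(model$net, X, train = FALSE)$probs
    labels <- max.col(probs, ties.method = "first") - 1L
  } else if (inherits(model, "hyse_cnn")) {
    X <- if (is.list(patches)) .cnn_feature_matrix(patches) else
      .cnn_feature_matrix(patches)
    probs <- .cnn_predict_matrix(model, X)
    labels <- max.col(probs, ties.method = "first") - 1L
  } else {
    binned <- if (is.list(patches)) attr(patches, "binned") else patches
    if (is.null(binned)) binned <- t(vapply(patches, unwrap_patch, numeric(121L)))
    pr <- predict_spectra(model, binned, ...)
    probs <- pr$scores
    labels <- pr$labels
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(
    list(labels = as.integer(labels), probabilities = probs,
         per_slice_seconds = elapsed),
    class = "classification_result"
  )
}

#' Classify a whole hypercube slice by slice
#'
#' Runs the online chain ([prepare_slice()] then [classify_slice()]) over
#' every scan step, recording preprocessing and classification time per
#' slice.
#'
#' @param model a trained `hyse_model`.
#' @param cube a raw-count [hypercube()].
#' @param cal a [calibration_frames()].
#' @param legend legend for the output [label_map()] (defaults to the
#'   model's library, if attached).
#' @param n_bins,median_size preprocessing parameters.
#' @param ... passed to the family's prediction routine.
#' @return list with `labels` (a [label_map()]), `per_slice_seconds`,
#'   `preprocess_seconds` and `fps` (from the combined per-slice time).
#' @export
classify_cube <- function(model, cube, cal, legend = NULL, n_bins = 121L,
                          median_size = 7L, ...) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  labels <- matrix(0L, d[1L], d[2L])
  t_pre <- numeric(d[1L])
  t_cls <- numeric(d[1L])
  for (x in seq_len(d[1L])) {
    patches <- prepare_slice(cube$data[x, , , drop = TRUE], cal,
                             n_bins = n_bins, median_size = median_size)
    res <- classify_slice(model, patches, ...)
    labels[x, ] <- res$labels
    t_pre[x] <- attr(patches, "preprocess_seconds")
    t_cls[x] <- res$per_slice_seconds
  }
  if (is.null(legend)) {
    legend <- if (!is.null(model$library)) {
      stats::setNames(c("background", model$library$names),
                      as.character(0:length(model$library$names)))
    } else {
      stats::setNames(as.character(sort(unique(as.vector(labels)))),
                      as.character(sort(unique(as.vector(labels)))))
    }
  }
  list(
    labels = label_map(labels, legend),
    per_slice_seconds = t_cls,
    preprocess_seconds = t_pre,
    fps = 1 / mean(t_pre + t_cls)
  )
}

#' Group-aware cross-validation folds
#'
#' Assigns base-cube groups to `k` folds so that all augmented copies of a
#' base cube land in the same fold (no train/validation leakage through
#' shared provenance) and fold sizes differ by at most one group.
#'
#' @param base_ids integer/character vector: provenance group of every cube
#'   in the pool.
#' @param k number of folds.
#' @param seed integer RNG seed for the group shuffle.
#' @return integer fold assignment (1..k) per cube.
#' @export
cv_folds <- function(base_ids, k = 5L, seed = 1L) {
  groups <- unique(base_ids)
  if (k > length(base_ids)) stop("k exceeds the pool size")
  if (k > length(groups)) stop("k exceeds the number of base-cube groups")
  with_seed(seed, {
    shuffled <- sample(groups)
    fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(groups)),
                                     as.character(shuffled))
    as.integer(fold_of_group[as.character(base_ids)])
  })
}

#' Cross-validate the pixel-wise CNN on a cube pool
#'
#' Splits the pool into `k` group-aware folds ([cv_folds()]), trains on the
#' remaining folds and scores held-out ACC_av per fold.
#'
#' @param pool list of entries, each `list(binned = (n_pixels x 121) matrix,
#'   labels = integer vector, base_id = provenance group)` (see
#'   [preprocess_cube()]).
#' @param k number of folds (default 5).
#' @param arch a pixel [cnn_architecture()].
#' @param config a [training_config()].
#' @param folds_to_run which folds to actually train (default all; a subset
#'   keeps exploratory runs cheap).
#' @param train_pixels_per_cube training patches sampled per cube.
#' @param eval_pixels_per_cube held-out pixels scored per validation cube
#'   (`Inf` = all).
#' @param seed integer RNG seed for fold assignment and pixel sampling.
#' @return list with `folds`, per-fold `reports` (ACC_av and confusion), and
#'   `acc_mean`/`acc_sd` over the folds run.
#' @export
cross_validate <- function(pool, k = 5L, arch = cnn_architecture("pixel"),
                           config = training_config(), folds_to_run = NULL,
                           train_pixels_per_cube = 200L,
                           eval_pixels_per_cube = 2000L, seed = 1L) {
  base_ids <- vapply(pool, function(e) as.character(e$base_id), character(1L))
  folds <- cv_folds(base_ids, k = k, seed = seed)
  if (is.null(folds_to_run)) folds_to_run <- seq_len(k)
  reports <- list()
  accs <- numeric(0)
  for (f in folds_to_run) {
    fit <- .fit_fold(pool, folds != f, folds == f, arch, config,
                     train_pixels_per_cube, eval_pixels_per_cube,
                     seed + 17L * f)
    reports[[as.character(f)]] <- fit
    accs <- c(accs, fit$acc_av)
  }
  list(folds = folds, reports = reports,
       acc_mean = mean(accs), acc_sd = stats::sd(accs))
}

# train on `tr` entries, evaluate ACC_av on `va` entries
.fit_fold <- function(pool, tr, va, arch, config, train_px, eval_px, seed) {
  sample_pixels <- function(entry, n_px) {
    n <- length(entry$labels)
    idx <- if (is.finite(n_px) && n_px < n)
      with_seed(seed + entry$base_id, sample.int(n, n_px)) else seq_len(n)
    list(x = entry$binned[idx, , drop = FALSE], y = entry$labels[idx])
  }
  tr_parts <- lapply(pool[tr], sample_pixels, n_px = train_px)
  Xtr <- do.call(rbind, lapply(tr_parts, `[[`, "x"))
  ytr <- unlist(lapply(tr_parts, `[[`, "y"))
  model <- build_pixel_cnn(arch, seed = seed)
  model <- train_cnn(model, Xtr, ytr, config)
  va_parts <- lapply(pool[va], sample_pixels, n_px = eval_px)
  Xva <- do.call(rbind, lapply(va_parts, `[[`, "x"))
  yva <- unlist(lapply(va_parts, `[[`, "y"))
  probs <- .cnn_predict_matrix(model, .cnn_feature_matrix(Xva))
  pred <- max.col(probs, ties.method = "first") - 1L
  rep <- accuracy(
    label_map(matrix(pred, nrow = 1L), .legend_for(max(c(pred, yva)))),
    label_map(matrix(yva, nrow = 1L), .legend_for(max(c(pred, yva))))
  )
  list(acc_av = rep$acc_av, confusion = rep$confusion, model = model,
       n_train = nrow(Xtr), n_eval = nrow(Xva))
}

.legend_for <- function(max_label) {
  stats::setNames(c("background", paste0("class_", seq_len(max_label))),
                  as.character(0:max_label))
}
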