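ns <- asNamespace("hyseclass")

# small separable patch set: 4 color classes + background, light noise
make_separable_set <- function(n_per_class = 100L, classes = c(1L, 2L, 7L, 8L),
                               seed = 21L, noise_sd = 0.01,
                               with_background = TRUE) {
  lib <- tiny_library()
  refs <- hyseclass:::.binned_refs(lib, 121L)
  hyseclass:::with_seed(seed, {
    X <- do.call(rbind, lapply(classes, function(k) {
      t(sapply(seq_len(n_per_class), function(i)
        pmax(refs[k, ] + rnorm(121, sd = noise_sd), 0)))
    }))
    y <- rep(classes, each = n_per_class)
    if (with_background) {
      Xb <- matrix(pmax(rnorm(n_per_class * 121, mean = 0.02, sd = noise_sd), 0),
                   n_per_class, 121)
      X <- rbind(X, Xb)
      y <- c(y, rep(0L, n_per_class))
    }
    list(X = X, y = y)
  })
}

test_that("architecture constructors enforce the layer structure", {
  expect_error(cnn_architecture("pixel", conv_filters = c(8, 8, 8)),
               "2 convolutional")
  expect_error(cnn_architecture("slice", conv_filters = c(8, 8)),
               "4 convolutional")
  a <- cnn_architecture("pixel")
  expect_identical(a$conv_filters, c(32L, 64L))
  expect_equal(a$dropout_rate, 0.40)
  expect_identical(a$n_outputs, 19L)
  expect_error(build_pixel_cnn(cnn_architecture("slice")), "pixel")
  expect_error(build_slice_cnn(cnn_architecture("pixel"), ny = 16), "slice")
})

test_that("forward pass emits a 19-way softmax summing to one", {
  m <- build_pixel_cnn(seed = 1)
  set.seed(2)
  X <- ns$.cnn_feature_matrix(matrix(runif(5 * 121), 5, 121))
  probs <- ns$.net_forward(m$net, X, train = FALSE)$probs
  expect_identical(dim(probs), c(5L, 19L))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-5)
  expect_true(all(probs >= 0))
})

test_that("initialization and inference are deterministic given the seed", {
  m1 <- build_pixel_cnn(seed = 33)
  m2 <- build_pixel_cnn(seed = 33)
  expect_identical(ns$.net_get_params(m1$net), ns$.net_get_params(m2$net))
  m3 <- build_pixel_cnn(seed = 34)
  expect_false(identical(ns$.net_get_params(m1$net), ns$.net_get_params(m3$net)))
  # dropout disabled at inference: repeated forwards agree exactly
  set.seed(3)
  X <- ns$.cnn_feature_matrix(matrix(runif(4 * 121), 4, 121))
  p1 <- ns$.net_forward(m1$net, X, train = FALSE)$probs
  p2 <- ns$.net_forward(m1$net, X, train = FALSE)$probs
  expect_identical(p1, p2)
})

test_that("a zero learning rate leaves all parameters unchanged", {
  d <- make_separable_set(n_per_class = 30L)
  m <- build_pixel_cnn(seed = 5)
  before <- ns$.net_get_params(m$net)
  trained <- train_cnn(m, d$X, d$y,
                       training_config(learning_rate = 0, max_epochs = 3L,
                                       seed = 6L))
  expect_identical(ns$.net_get_params(trained$net), before)
})

test_that("backpropagation gradients match finite differences", {
  arch <- cnn_architecture("pixel", conv_filters = c(2L, 3L), fc_width = 5L,
                           n_outputs = 4L, dropout_rate = 0,
                           l2_coefficient = 1e-3)
  m <- build_pixel_cnn(arch, seed = 2)
  set.seed(1)
  X <- matrix(runif(6 * 121), 6, 121)
  Y <- ns$.one_hot(sample(0:3, 6, replace = TRUE), 4L)
  net <- m$net
  fwd <- ns$.net_forward(net, X, train = FALSE)
  g <- ns$.net_grad_vector(net, ns$.net_backward(net, fwd, Y))
  theta <- ns$.net_get_params(net)
  loss_at <- function(th) {
    n2 <- ns$.net_set_params(net, th)
    f <- ns$.net_forward(n2, X, train = FALSE)
    ns$.net_loss(n2, f$probs, Y)
  }
  idx <- sample(length(theta), 40)
  num <- vapply(idx, function(i) {
    e <- rep(0, length(theta)); e[i] <- 1e-5
    (loss_at(theta + e) - loss_at(theta - e)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(num - g[idx])), 1e-4)
})

test_that("one SGD step without momentum moves exactly -lr * gradient", {
  arch <- cnn_architecture("pixel", conv_filters = c(2L, 2L), fc_width = 4L,
                           n_outputs = 3L, dropout_rate = 0,
                           l2_coefficient = 0)
  m <- build_pixel_cnn(arch, seed = 9)
  set.seed(4)
  X <- matrix(runif(5 * 121), 5, 121)
  Y <- ns$.one_hot(sample(0:2, 5, replace = TRUE), 3L)
  net <- m$net
  theta0 <- ns$.net_get_params(net)
  fwd <- ns$.net_forward(net, X, train = FALSE)
  g <- ns$.net_grad_vector(net, ns$.net_backward(net, fwd, Y))
  lr <- 0.01
  net2 <- ns$.net_sgd_step(net, ns$.net_backward(net, fwd, Y), lr, 0)
  expect_equal(ns$.net_get_params(net2), theta0 - lr * g, tolerance = 1e-12)
})

test_that("the pixel CNN overfits a tiny separable set", {
  d <- make_separable_set(n_per_class = 80L)
  m <- build_pixel_cnn(seed = 7, library = tiny_library())
  m <- train_cnn(m, d$X, d$y,
                 training_config(max_epochs = 200L, patience = 15L, seed = 8L))
  expect_lte(m$epochs_run, 200L)
  pred <- max.col(ns$.cnn_predict_matrix(m, ns$.cnn_feature_matrix(d$X)),
                  ties.method = "first") - 1L
  expect_gte(mean(pred == d$y), 0.99)
  # loss decreases after smoothing (descent sanity)
  sm <- stats::filter(m$log$loss, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("training rejects labels outside the output range", {
  d <- make_separable_set(n_per_class = 5L)
  m <- build_pixel_cnn(seed = 1)
  expect_error(train_cnn(m, d$X, d$y + 20L, training_config(max_epochs = 1L)),
               "labels")
  expect_error(classify_slice(m, matrix(runif(121), 1, 121)), "trained")
})

test_that("classify_slice labels pure-class noiseless pixels correctly", {
  r <- tiny_render(nx = 4L, ny = 48L, nl = 242L, noise_sd = 0.003,
                   artifact_frac = 0.005)
  pp <- preprocess_cube(r$cube, r$cal)
  lab <- as.vector(r$labels$labels)
  # background training includes synthesized dark/cladding/mixture exemplars
  bg <- synthesize_background_spectra(tiny_library(), 60L, seed = 14L)
  m <- build_pixel_cnn(seed = 15, library = tiny_library())
  m <- train_cnn(m, rbind(pp$binned, bg), c(lab, rep(0L, nrow(bg))),
                 training_config(max_epochs = 120L, patience = 10L, seed = 16L))
  patches <- prepare_slice(r$cube$data[2, , ], r$cal)
  res <- classify_slice(m, patches)
  expect_s3_class(res, "classification_result")
  expect_gt(res$per_slice_seconds, 0)
  expect_equal(rowSums(res$probabilities), rep(1, 48), tolerance = 1e-5)
  truth <- r$labels$labels[2, ]
  interior <- truth > 0
  expect_gte(mean(res$labels[interior] == truth[interior]), 0.9)
  # dark pixels (margins trained as background) -> background label
  dark_patch <- matrix(0, 3, 121)
  expect_true(all(classify_slice(m, dark_patch)$labels == 0L))
})

test_that("the slice-wise CNN emits one label per line pixel", {
  m1 <- build_slice_cnn(ny = 24L, seed = 19)
  m2 <- build_slice_cnn(ny = 24L, seed = 19)
  expect_identical(ns$.net_get_params(m1$net), ns$.net_get_params(m2$net))
  set.seed(20)
  X <- array(runif(6 * 24 * 121), c(6, 24, 121))
  y <- matrix(sample(0:18, 6 * 24, replace = TRUE), 6, 24)
  m1 <- train_cnn(m1, X, y, training_config(max_epochs = 2L, batch_size = 3L,
                                            seed = 21L))
  res <- classify_slice(m1, matrix(runif(24 * 121), 24, 121))
  expect_length(res$labels, 24L)
  expect_equal(rowSums(res$probabilities), rep(1, 24), tolerance = 1e-5)
})

test_that("slice-wise accuracy lands close to pixel-wise on a separable task", {
  # shared task: slices assembled from the same 4-class spectra
  lib <- tiny_library()
  refs <- hyseclass:::.binned_refs(lib, 121L)
  classes <- c(1L, 2L, 7L, 8L)
  ny <- 16L
  make_slices <- function(n, seed) {
    hyseclass:::with_seed(seed, {
      X <- array(0, c(n, ny, 121))
      y <- matrix(0L, n, ny)
      for (i in seq_len(n)) {
        half <- sample(classes, 2L)
        y[i, ] <- rep(half, each = ny / 2)
        X[i, , ] <- t(sapply(y[i, ], function(k)
          pmax(refs[k, ] + rnorm(121, sd = 0.01), 0)))
      }
      list(X = X, y = y)
    })
  }
  tr <- make_slices(60L, seed = 31L)
  te <- make_slices(20L, seed = 32L)
  ms <- build_slice_cnn(ny = ny, seed = 33)
  ms <- train_cnn(ms, tr$X, tr$y,
                  training_config(max_epochs = 60L, patience = 10L,
                                  batch_size = 10L, seed = 34L))
  Xte <- te$X
  dim(Xte) <- c(dim(te$X)[1], ny * 121L)
  probs <- ns$.net_forward(ms$net, Xte, train = FALSE)$probs
  pred <- max.col(probs, ties.method = "first") - 1L
  acc_slice <- mean(pred == as.vector(te$y))

  d <- make_separable_set(n_per_class = 60L, with_background = FALSE)
  mp <- build_pixel_cnn(seed = 35)
  mp <- train_cnn(mp, d$X, d$y,
                  training_config(max_epochs = 60L, patience = 10L, seed = 36L))
  te_px <- make_separable_set(n_per_class = 30L, seed = 37L,
                              with_background = FALSE)
  pred_px <- max.col(ns$.cnn_predict_matrix(mp, ns$.cnn_feature_matrix(te_px$X)),
                     ties.method = "first") - 1L
  acc_pixel <- mean(pred_px == te_px$y)
  expect_gte(acc_slice, acc_pixel - 0.05)
})

test_that("cross-validation folds partition the pool without leakage", {
  base_ids <- c(1:12, sample(1:12, 60, replace = TRUE))
  folds <- cv_folds(base_ids, k = 5L, seed = 3L)
  expect_length(folds, 72L)
  expect_setequal(unique(folds), 1:5)
  # all cubes of one base group share a fold
  for (g in 1:12) expect_length(unique(folds[base_ids == g]), 1L)
  # balanced in groups: fold group counts differ by at most 1
  per_fold_groups <- vapply(1:5, function(f)
    length(unique(base_ids[folds == f])), integer(1))
  expect_lte(diff(range(per_fold_groups)), 1L)
  expect_error(cv_folds(1:4, k = 5L), "k exceeds")
})

test_that("cross_validate trains per fold and reports fold accuracies", {
  lib <- tiny_library()
  geom <- scene_geometry("planar")
  pool <- simulate_training_pool(
    chart_spec(), lib, geom, n_replicates = 1L,
    params = augmentation_params(n_augmented = 5L, seed = 2L),
    sections = c(1L, 2L), seed = 40L, nx = 3L, ny = 32L, nl = 150L
  )
  cv <- cross_validate(pool$entries, k = 2L,
                       config = training_config(max_epochs = 30L,
                                                patience = 5L, seed = 41L),
                       folds_to_run = 1L, train_pixels_per_cube = 60L,
                       eval_pixels_per_cube = 60L, seed = 42L)
  expect_length(cv$folds, length(pool$entries))
  expect_true(is.finite(cv$acc_mean))
  expect_gte(cv$acc_mean, 0)
  expect_lte(cv$acc_mean, 100)
})
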