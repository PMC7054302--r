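lib <- tiny_library()
refs121 <- hyseclass:::.binned_refs(lib, 121L)

test_that("Pearson matching recovers exact and anti-correlated references", {
  model <- pearson_model(lib)
  for (k in c(1L, 9L, 18L)) {
    r <- pearson_classify(refs121[k, ], model)
    expect_identical(r$label, k)
    expect_equal(r$score, 1)
  }
  # negated reference: correlation -1, that class cannot win
  r <- predict_spectra(model, matrix(1 - refs121[3, ], nrow = 1))
  cm <- stats::cor(1 - refs121[3, ], refs121[3, ])
  expect_equal(cm, -1)
  expect_false(r$labels[1] == 3L)
})

test_that("Pearson coefficient equals the covariance-formula oracle", {
  a <- c(1, 2, 3)
  b <- c(1, 2, 3.5)
  # direct transcription of the definition
  rho <- sum((a - mean(a)) / sd(a) * (b - mean(b)) / sd(b)) / (length(a) - 1)
  expect_equal(stats::cor(a, b), rho)
  set.seed(5)
  m <- pearson_model(lib, n_bins = 121L, threshold = -Inf)
  for (i in 1:10) {
    s <- runif(121)
    oracle <- apply(refs121, 1L, function(rr) {
      sum((s - mean(s)) / sd(s) * (rr - mean(rr)) / sd(rr)) / 120
    })
    got <- pearson_classify(s, m)
    expect_equal(got$label, which.max(oracle))
    expect_equal(got$score, max(oracle))
  }
})

test_that("Pearson is invariant to positive affine rescaling of the input", {
  model <- pearson_model(lib)
  set.seed(8)
  s <- refs121[5, ] + rnorm(121, sd = 0.01)
  base <- predict_spectra(model, matrix(s, nrow = 1))
  for (scale in c(0.2, 3)) for (shift in c(0, 0.4)) {
    r <- predict_spectra(model, matrix(scale * s + shift, nrow = 1))
    expect_identical(r$labels, base$labels)
    expect_equal(r$scores, base$scores)
  }
})

test_that("zero-variance spectra fall back to the background label", {
  model <- pearson_model(lib)
  r <- pearson_classify(rep(0.3, 121), model)
  expect_identical(r$label, 0L)
  expect_true(is.na(r$score))
})

test_that("supervised unmixing recovers pure endmembers one-hot", {
  model <- unmix_supervised_model(lib)
  for (k in c(2L, 11L, 17L)) {
    r <- unmix_supervised(refs121[k, ], model)
    expect_identical(r$label, k)
    one_hot <- replace(rep(0, 18), k, 1)
    expect_equal(r$abundances, one_hot, tolerance = 1e-6)
  }
})

test_that("supervised unmixing recovers a 50/50 two-endmember mixture", {
  model <- unmix_supervised_model(lib)
  mix <- 0.5 * refs121[4, ] + 0.5 * refs121[13, ]
  r <- unmix_supervised(mix, model)
  expect_equal(r$abundances[4], 0.5, tolerance = 1e-3)
  expect_equal(r$abundances[13], 0.5, tolerance = 1e-3)
  expect_equal(sum(r$abundances[-c(4, 13)]), 0, tolerance = 1e-3)
})

test_that("the all-zero spectrum unmixes to zero abundances and background", {
  r <- unmix_supervised(rep(0, 121), unmix_supervised_model(lib))
  expect_equal(r$abundances, rep(0, 18))
  expect_identical(r$label, 0L)
})

test_that("full unmixing residual never exceeds the best single-endmember fit", {
  model <- unmix_supervised_model(lib)
  set.seed(3)
  for (i in 1:5) {
    s <- 0.6 * refs121[sample(18, 1), ] + 0.3 * refs121[sample(18, 1), ] +
      rnorm(121, sd = 0.02)
    s <- pmax(s, 0)
    ab <- unmix_supervised(s, model)$abundances
    full_res <- sum((s - as.vector(t(refs121) %*% ab))^2)
    single_res <- min(vapply(1:18, function(k) {
      coef <- max(0, sum(s * refs121[k, ]) / sum(refs121[k, ]^2))
      sum((s - coef * refs121[k, ])^2)
    }, numeric(1)))
    expect_lte(full_res, single_res + 1e-10)
  }
})

test_that("duplicate references make the unmixing design singular", {
  dup <- reference_library(
    c("a", "b"), rbind(lib$spectra[1, ], lib$spectra[1, ]),
    lib$rgb[1:2, ], lib$wavelengths
  )
  expect_error(unmix_supervised_model(dup), "singular|collinear")
})

test_that("NMF unmixing recovers two pure classes from a synthetic cube", {
  set.seed(10)
  n_px <- 120
  V <- rbind(
    t(sapply(runif(n_px / 2, 0.7, 1.3), function(a) a * refs121[3, ])),
    t(sapply(runif(n_px / 2, 0.7, 1.3), function(a) a * refs121[16, ]))
  ) + matrix(rnorm(n_px * 121, sd = 1e-3), n_px, 121)
  V <- pmax(V, 0)
  fit <- unmix_unsupervised(V, lib, k = 2L, n_iter = 300L, seed = 4L)
  cors <- stats::cor(t(fit$endmembers), t(refs121[c(3, 16), ]))
  expect_true(all(apply(cors, 1L, max) > 0.99))
  expect_setequal(fit$class_of_endmember, c(3L, 16L))
  truth <- rep(c(3L, 16L), each = n_px / 2)
  expect_gt(mean(fit$labels == truth), 0.98)
})

test_that("NMF objective is non-increasing and seeded runs are identical", {
  set.seed(2)
  V <- matrix(runif(40 * 50), 40, 50)
  f1 <- unmix_unsupervised(V, lib, k = 4L, n_bins = 50L, n_iter = 80L,
                           seed = 6L)
  f2 <- unmix_unsupervised(V, lib, k = 4L, n_bins = 50L, n_iter = 80L,
                           seed = 6L)
  expect_true(all(diff(f1$objective) <= 1e-8))
  expect_identical(f1$endmembers, f2$endmembers)
  expect_identical(f1$abundances, f2$abundances)
  expect_error(unmix_unsupervised(V, lib, k = 100L), "pixels")
})

test_that("one-vs-one SVM trains k(k-1)/2 binary classifiers", {
  set.seed(11)
  X4 <- do.call(rbind, lapply(1:4, function(k)
    t(sapply(1:20, function(i) refs121[k, ] + rnorm(121, sd = 0.01)))))
  y4 <- rep(1:4, each = 20)
  m4 <- svm_train(X4, y4)
  expect_identical(m4$n_binary, 6L)
  # libsvm keeps one decision offset per binary problem
  expect_length(m4$fit$rho, 6L)
  expect_error(svm_train(X4[1:20, ], y4[1:20]), "2 classes")
})

test_that("SVM separates a linearly separable 2-class toy set exactly", {
  set.seed(12)
  X <- rbind(matrix(rnorm(60, mean = 0), ncol = 2),
             matrix(rnorm(60, mean = 6), ncol = 2))
  y <- rep(c(0L, 1L), each = 30)
  m <- svm_train(X, y)
  expect_equal(svm_classify(m, X), y)
  expect_identical(m$n_binary, 1L)
})

test_that("18-class SVM instantiates 153 binary problems", {
  set.seed(13)
  X <- do.call(rbind, lapply(1:18, function(k)
    t(sapply(1:6, function(i) refs121[k, ] + rnorm(121, sd = 0.01)))))
  y <- rep(1:18, each = 6)
  m <- svm_train(X, y)
  expect_identical(m$n_binary, 153L)
  expect_length(m$fit$rho, 153L)
})
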