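# Conventional spectral baselines under a uniform per-pixel contract.
#
# Library reference spectra are evaluated on the equispaced bin-center grid
# spanning the library's wavelength range, so they line up with index-binned
# cube spectra regardless of the library's native tabulation density.
#
# All families consume binned 121-sample spectra (the same representation
# the CNN sees) and emit one label per pixel, 0 meaning background. Winning
# scores below a per-family threshold fall back to background: Pearson
# correlation < 0.5, maximum abundance < 0.2 (both configurable), so the
# families remain comparable with the CNN's trained background class.

# original class labels of a (possibly subset) library's rows
.library_class_ids <- function(library) {
  ids <- attr(library, "class_ids")
  if (is.null(ids)) seq_along(library$names) else ids
}

# reference spectra on the n_bins equispaced bin-center grid
.binned_refs <- function(library, n_bins) {
  grid <- seq(min(library$wavelengths), max(library$wavelengths),
              length.out = n_bins)
  resample_library(library, grid)$spectra
}

#' Uniform per-pixel prediction contract
#'
#' @param model a `hyse_model` (any baseline family).
#' @param spectra numeric matrix, one binned spectrum per row.
#' @param ... family-specific options.
#' @return list with `labels` (integer, 0 = background) and `scores` (the
#'   winning statistic per pixel, or a per-class score matrix).
#' @export
predict_spectra <- function(model, spectra, ...) UseMethod("predict_spectra")

# --- Pearson correlation matching -------------------------------------------

#' Pearson correlation classifier
#'
#' Matches each pixel spectrum to the library entry with the highest Pearson
#' correlation coefficient; ties break to the lowest class index. Pixels
#' with zero spectral variance (the coefficient is undefined) and pixels
#' whose winning correlation falls below `threshold` are labeled background.
#'
#' @param library a [reference_library()].
#' @param n_bins spectral bin count the classifier operates on (default
#'   121).
#' @param threshold background threshold on the winning correlation
#'   (default 0.5).
#' @return a `hyse_model` of family `pearson`.
#' @export
pearson_model <- function(library, n_bins = 121L, threshold = 0.5) {
  stopifnot(inherits(library, "reference_library"))
  refs <- .binned_refs(library, n_bins)
  structure(
    list(family = "pearson", refs = refs, library = library,
         class_ids = .library_class_ids(library),
         n_bins = as.integer(n_bins), threshold = threshold, trained = TRUE),
    class = c("hyse_pearson", "hyse_model")
  )
}

#' @export
predict_spectra.hyse_pearson <- function(model, spectra, ...) {
  spectra <- as.matrix(spectra)
  sds <- apply(spectra, 1L, stats::sd)
  ok <- sds > 0
  labels <- integer(nrow(spectra))
  scores <- rep(NA_real_, nrow(spectra))
  if (any(ok)) {
    cm <- stats::cor(t(spectra[ok, , drop = FALSE]), t(model$refs))
    win <- max.col(cm, ties.method = "first")
    rho <- cm[cbind(seq_len(nrow(cm)), win)]
    lab <- ifelse(rho < model$threshold, 0L, model$class_ids[win])
    labels[ok] <- lab
    scores[ok] <- rho
  }
  list(labels = labels, scores = scores)
}

#' Classify a single spectrum by Pearson correlation
#'
#' @param pixel_spectrum numeric vector on the model's bin grid.
#' @param library a [reference_library()] (or a prebuilt [pearson_model()]).
#' @param n_bins bin count used when `library` is a raw library.
#' @return list with `label` (0 = background) and `score` (winning
#'   correlation, `NA` for zero-variance input).
#' @export
pearson_classify <- function(pixel_spectrum, library, n_bins = length(pixel_spectrum)) {
  model <- if (inherits(library, "hyse_pearson")) library else
    pearson_model(library, n_bins = n_bins)
  r <- predict_spectra(model, matrix(pixel_spectrum, nrow = 1L))
  list(label = r$labels[1L], score = r$scores[1L])
}

# --- supervised unmixing (non-negative least squares) -----------------------

#' Supervised spectral unmixing classifier
#'
#' Solves a non-negative least-squares fit of each pixel spectrum against
#' the 18 library reference spectra (non-negativity enforced, sum-to-one
#' not: illumination variation scales abundances). The label is the
#' endmember of maximum abundance; pixels whose maximum abundance falls
#' below `threshold` are background.
#'
#' @param library a [reference_library()].
#' @param n_bins spectral bin count (default 121).
#' @param threshold background threshold on the maximum abundance (default
#'   0.2).
#' @return a `hyse_model` of family `unmix_supervised`.
#' @export
unmix_supervised_model <- function(library, n_bins = 121L, threshold = 0.2) {
  stopifnot(inherits(library, "reference_library"))
  refs <- .binned_refs(library, n_bins)
  C <- t(refs)                     # n_bins x n_classes design
  if (qr(C)$rank < ncol(C)) {
    stop("reference spectra are collinear; the unmixing design is singular")
  }
  structure(
    list(family = "unmix_supervised", design = C, library = library,
         class_ids = .library_class_ids(library),
         n_bins = as.integer(n_bins), threshold = threshold, trained = TRUE),
    class = c("hyse_unmix_sup", "hyse_model")
  )
}

#' @export
predict_spectra.hyse_unmix_sup <- function(model, spectra, ...) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  k <- ncol(model$design)
  ab <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ab[i, ] <- pracma::lsqnonneg(model$design, as.numeric(spectra[i, ]))$x
  }
  win <- max.col(ab, ties.method = "first")
  amax <- ab[cbind(seq_len(n), win)]
  labels <- ifelse(amax < model$threshold, 0L, model$class_ids[win])
  list(labels = labels, scores = amax, abundances = ab)
}

#' Unmix a single spectrum against the library
#'
#' @param pixel_spectrum numeric vector on the model's bin grid.
#' @param library a [reference_library()] or prebuilt
#'   [unmix_supervised_model()].
#' @param n_bins bin count used when `library` is a raw library.
#' @return list with `abundances` (non-negative vector over the endmembers),
#'   `label` (0 = background) and `score` (max abundance).
#' @export
unmix_supervised <- function(pixel_spectrum, library,
                             n_bins = length(pixel_spectrum)) {
  model <- if (inherits(library, "hyse_unmix_sup")) library else
    unmix_supervised_model(library, n_bins = n_bins)
  r <- predict_spectra(model, matrix(pixel_spectrum, nrow = 1L))
  list(abundances = as.numeric(r$abundances[1L, ]), label = r$labels[1L],
       score = r$scores[1L])
}

# --- unsupervised unmixing (non-negative matrix factorization) --------------

#' Unsupervised spectral unmixing of a cube
#'
#' Factorizes the pixels-by-channels matrix `V` into non-negative abundances
#' `W` (pixels x k) and endmembers `H` (k x channels) by multiplicative
#' updates minimizing the Frobenius reconstruction error, with a fixed
#' iteration cap and seeded initialization. Discovered endmembers are
#' matched to library classes by maximum Pearson correlation; each pixel is
#' labeled with the matched class of its largest abundance (background when
#' that abundance is below `threshold`).
#'
#' @param x a [hypercube()] of reflectance, or a pixels-by-channels matrix
#'   of binned spectra.
#' @param library a [reference_library()] for endmember matching.
#' @param k number of endmembers (default 18).
#' @param n_bins spectral bin count when `x` is a cube (default 121).
#' @param n_iter multiplicative-update iterations (default 200).
#' @param threshold background threshold on the winning abundance.
#' @param match_threshold endmembers whose best library correlation falls
#'   below this are treated as background material (margins, shadows).
#' @param seed integer RNG seed for the initialization.
#' @return list with `endmembers` (k x channels), `abundances` (pixels x k),
#'   `labels` (integer per pixel), `class_of_endmember`, and `objective`
#'   (reconstruction error per iteration, non-increasing).
#' @export
unmix_unsupervised <- function(x, library, k = 18L, n_bins = 121L,
                               n_iter = 200L, threshold = 0.2,
                               match_threshold = 0.7, seed = 1L) {
  stopifnot(inherits(library, "reference_library"))
  V <- if (inherits(x, "hypercube")) {
    d <- dim(x$data)
    flat <- x$data
    dim(flat) <- c(d[1L] * d[2L], d[3L])
    .bin_matrix(flat, n_bins)
  } else as.matrix(x)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(V)) stop("k exceeds the number of pixels")
  V <- pmax(V, 0)
  eps <- 1e-9
  with_seed(seed, {
    W <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    # seed endmembers at mutually dissimilar extreme pixels (furthest-point
    # heuristic on the spectra): keeps the factorization near pure
    # endmembers, where fully random factors often converge to blends
    picked <- which.max(rowSums(V^2))
    if (k > 1L) {
      sds <- apply(V, 1L, stats::sd)
      usable <- which(sds > 0)
      for (j in 2L:k) {
        cand <- setdiff(usable, picked)
        if (length(cand) == 0L) cand <- setdiff(seq_len(nrow(V)), picked)
        cc <- suppressWarnings(
          stats::cor(t(V[cand, , drop = FALSE]), t(V[picked, , drop = FALSE])))
        cc[is.na(cc)] <- 1
        worst <- apply(cc, 1L, max)
        picked <- c(picked, cand[which.min(worst)])
      }
    }
    H <- V[picked, , drop = FALSE] + 0.01
    objective <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      objective[it] <- sqrt(sum((V - W %*% H)^2))
    }
    # scale endmembers to unit maximum, absorbing scale into abundances
    scale <- pmax(apply(H, 1L, max), eps)
    H <- H / scale
    W <- sweep(W, 2L, scale, "*")
    refs <- .binned_refs(library, ncol(V))
    cm <- suppressWarnings(stats::cor(t(H), t(refs)))
    cm[is.na(cm)] <- -1
    class_of <- max.col(cm, ties.method = "first")
    best_cor <- cm[cbind(seq_len(k), class_of)]
    ids <- .library_class_ids(library)
    class_of <- ifelse(best_cor < match_threshold, 0L, ids[class_of])
    win <- max.col(W, ties.method = "first")
    amax <- W[cbind(seq_len(nrow(W)), win)]
    labels <- ifelse(amax < threshold, 0L, class_of[win])
    list(endmembers = H, abundances = W, labels = labels,
         class_of_endmember = class_of, objective = objective)
  })
}

#' Unsupervised unmixing classifier wrapper
#'
#' Fits [unmix_unsupervised()] lazily per input batch under the uniform
#' prediction contract. `k` defaults to the library size.
#'
#' @param library a [reference_library()].
#' @param k endmember count.
#' @param n_iter,threshold,seed see [unmix_unsupervised()].
#' @return a `hyse_model` of family `unmix_unsupervised`.
#' @export
unmix_unsupervised_model <- function(library, k = 18L, n_iter = 200L,
                                     threshold = 0.2, match_threshold = 0.7,
                                     seed = 1L) {
  structure(
    list(family = "unmix_unsupervised", library = library, k = as.integer(k),
         n_iter = as.integer(n_iter), threshold = threshold,
         match_threshold = match_threshold, seed = as.integer(seed),
         trained = TRUE),
    class = c("hyse_unmix_unsup", "hyse_model")
  )
}

#' @export
predict_spectra.hyse_unmix_unsup <- function(model, spectra, ...) {
  fit <- unmix_unsupervised(as.matrix(spectra), model$library,
                            k = min(model$k, nrow(as.matrix(spectra))),
                            n_iter = model$n_iter,
                            threshold = model$threshold,
                            match_threshold = model$match_threshold,
                            seed = model$seed)
  win <- max.col(fit$abundances, ties.method = "first")
  list(labels = fit$labels,
       scores = fit$abundances[cbind(seq_along(win), win)],
       fit = fit)
}

# --- one-vs-one support vector machines -------------------------------------

#' Train a one-vs-one SVM classifier
#'
#' Trains `k (k - 1) / 2` binary maximum-margin classifiers (radial basis
#' kernel, libsvm's default scale heuristic) over all class pairs;
#' prediction is by majority vote with ties broken toward the lowest class
#' index.
#'
#' @param spectra numeric matrix of binned training spectra (rows).
#' @param labels integer labels (0 = background allowed as an ordinary
#'   class).
#' @param library optional [reference_library()] for display bookkeeping.
#' @param ... further arguments to [e1071::svm()].
#' @return a `hyse_model` of family `svm` with field `n_binary`.
#' @export
svm_train <- function(spectra, labels, library = NULL, ...) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("SVM training requires at least 2 classes")
  }
  fit <- e1071::svm(as.matrix(spectra), factor(labels, levels = classes),
                    kernel = "radial", ...)
  structure(
    list(family = "svm", fit = fit, classes = classes,
         n_binary = (length(classes) * (length(classes) - 1L)) %/% 2L,
         library = library, trained = TRUE),
    class = c("hyse_svm", "hyse_model")
  )
}

#' @export
predict_spectra.hyse_svm <- function(model, spectra, ...) {
  pred <- stats::predict(model$fit, as.matrix(spectra))
  labels <- as.integer(as.character(pred))
  list(labels = labels, scores = rep(NA_real_, length(labels)))
}

#' Classify spectra with a trained one-vs-one SVM
#'
#' @param model a model from [svm_train()].
#' @param spectrum numeric vector (one spectrum) or matrix of spectra.
#' @return integer label(s), 0 = background.
#' @export
svm_classify <- function(model, spectrum) {
  stopifnot(inherits(model, "hyse_svm"))
  m <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1L)
  predict_spectra(model, m)$labels
}
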