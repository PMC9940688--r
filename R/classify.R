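# SVM stage on key-region feature vectors.  Standardization statistics are
# fit on the training split only; the kernel machine itself is libsvm (via
# e1071) with an RBF kernel, C = 1 and the variance-scaled gamma by default.
# Multi-class handling is libsvm's pairwise voting.

#' Train/test split specification
#'
#' @param train_fraction fraction of samples used for training (0 < f < 1).
#' @param stratified draw the split per class, preserving class proportions
#'   to within one sample per class.
#' @param seed integer seed.
#' @return a `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  structure(list(train_fraction = train_fraction,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_spec")
}

#' SVM configuration
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param C soft-margin cost (> 0).
#' @param gamma RBF width, or `"scale"` for `1 / (d * var(x))` computed on the
#'   (standardized) training features.
#' @param standardize fit per-feature z-scores on the training split only.
#' @param seed integer seed (the fit itself is deterministic; the seed guards
#'   any tie-breaking).
#' @return an `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), C = 1, gamma = "scale",
                       standardize = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be positive")
  if (!identical(gamma, "scale") && !(is.numeric(gamma) && gamma > 0))
    stop("gamma must be positive or \"scale\"")
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "svm_config")
}

#' Stratified (or plain) train/test indices
#'
#' @param labels label vector.
#' @param spec a [split_spec()].
#' @return list with integer vectors `train` and `test`.
#' @export
split_indices <- function(labels, spec = split_spec()) {
  n <- length(labels)
  with_seed(spec$seed, {
    if (!spec$stratified) {
      ntr <- max(1L, min(n - 1L, round(spec$train_fraction * n)))
      tr <- sort(sample.int(n, ntr))
    } else {
      tr <- integer(0)
      for (lab in sort(unique(as.character(labels)))) {
        idx <- which(as.character(labels) == lab)
        k <- length(idx)
        ntr <- round(spec$train_fraction * k)
        ntr <- max(1L, min(k - 1L, ntr))
        if (k == 1L) ntr <- 1L
        tr <- c(tr, sort(sample(idx, ntr)))
      }
      tr <- sort(tr)
    }
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

#' Fit the SVM stage
#'
#' @param features numeric matrix, samples in rows.
#' @param labels label vector (>= 2 classes, >= 2 samples per class).
#' @param cfg an [svm_config()].
#' @return a `camfuse_svm` carrying the fitted machine and the
#'   standardization statistics.
#' @export
svm_fit <- function(features, labels, cfg = svm_config()) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) stop("need at least 2 classes to fit the classifier")
  if (any(table(y) < 2L)) stop("need at least 2 samples per class")
  center <- scl <- NULL
  x <- features
  if (cfg$standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scl, `/`)
  }
  g <- if (identical(cfg$gamma, "scale")) {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v < 1e-12) v <- 1
    1 / (ncol(x) * v)
  } else cfg$gamma
  fit <- with_seed(cfg$seed,
    e1071::svm(x = x, y = y, scale = FALSE,
               kernel = if (cfg$kernel == "rbf") "radial" else "linear",
               cost = cfg$C, gamma = g, probability = FALSE))
  structure(list(model = fit, center = center, scale = scl,
                 levels = levels(y), gamma = g, cfg = cfg,
                 n_features = ncol(features)),
            class = "camfuse_svm")
}

#' @export
print.camfuse_svm <- function(x, ...) {
  cat(sprintf("<camfuse_svm> %s kernel, C=%g, gamma=%.3g, %d classes, %d SVs\n",
              x$cfg$kernel, x$cfg$C, x$gamma, length(x$levels),
              x$model$tot.nSV))
  invisible(x)
}

#' Predict labels from a fitted SVM stage
#' @param object a `camfuse_svm`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.camfuse_svm <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$n_features)
    stop("feature dimension mismatch: model expects ", object$n_features,
         ", got ", ncol(newdata))
  x <- newdata
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  as.character(stats::predict(object$model, x))
}

#' Evaluate a fitted SVM stage on held-out data
#'
#' @param fit a `camfuse_svm`.
#' @param features held-out feature matrix.
#' @param labels held-out labels.
#' @return a [classification_report()] over the model's class universe.
#' @export
svm_evaluate <- function(fit, features, labels) {
  if (length(labels) == 0L || nrow(features) == 0L)
    stop("empty evaluation set")
  pred <- predict(fit, features)
  classification_report(labels, pred, class_names = fit$levels)
}

#' One-row summary of a fitted SVM stage
#' @param x a `camfuse_svm`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance camfuse_svm
#' @export
glance.camfuse_svm <- function(x, ...) {
  tibble::tibble(kernel = x$cfg$kernel, C = x$cfg$C, gamma = x$gamma,
                 n_classes = length(x$levels), n_support = x$model$tot.nSV,
                 n_features = x$n_features)
}

#' Persist / restore a fitted SVM stage (with its standardization statistics)
#' @param fit a `camfuse_svm`.
#' @param path RDS path.
#' @return `load_svm` returns the fitted object.
#' @export
save_svm <- function(fit, path) {
  stopifnot(inherits(fit, "camfuse_svm"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_svm
#' @export
load_svm <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "camfuse_svm"))
  fit
}
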