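# Fusion-quality statistics and classification reporting.
#
# Spatial frequency (SF) and average gradient (AG) both measure the amount of
# textural information in a fused image through first differences; the exact
# divisor conventions are fixed here:
#   RF = sqrt( sum of squared horizontal first differences / (M*N) )
#   CF = likewise vertical;  SF = sqrt(RF^2 + CF^2)
#   AG = mean over the (M-1)(N-1) interior grid of sqrt((dx^2 + dy^2) / 2)
# Intensities are first rescaled to [0, scale]; scale = 255 reproduces the
# 8-bit convention, scale = 1 the unit-range one (both conventions appear in
# the fusion literature, with AG typically quoted 8-bit).

#' Spatial frequency of a grayscale image
#'
#' @param image numeric matrix (at least 2 x 2).
#' @param scale intensity range the statistic is computed on (default 255,
#'   the 8-bit convention). Inputs are multiplied by `scale`.
#' @return nonnegative number; 0 iff the image is constant.
#' @export
spatial_frequency <- function(image, scale = 255) {
  stopifnot(is.matrix(image))
  M <- nrow(image); N <- ncol(image)
  if (M < 2L || N < 2L) stop("image must be at least 2 x 2")
  f <- image * scale
  rf2 <- sum((f[, -1L, drop = FALSE] - f[, -N, drop = FALSE])^2) / (M * N)
  cf2 <- sum((f[-1L, , drop = FALSE] - f[-M, , drop = FALSE])^2) / (M * N)
  sqrt(rf2 + cf2)
}

#' Average gradient of a grayscale image
#'
#' @inheritParams spatial_frequency
#' @return nonnegative number; 0 iff the image is constant.
#' @export
average_gradient <- function(image, scale = 255) {
  stopifnot(is.matrix(image))
  M <- nrow(image); N <- ncol(image)
  if (M < 2L || N < 2L) stop("image must be at least 2 x 2")
  f <- image * scale
  dx <- f[-M, -1L, drop = FALSE] - f[-M, -N, drop = FALSE]
  dy <- f[-1L, -N, drop = FALSE] - f[-M, -N, drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Fusion metrics for one image
#'
#' @inheritParams spatial_frequency
#' @return a one-row tibble with `sf`, `ag` and `scale`.
#' @export
fusion_metrics <- function(image, scale = 255) {
  tibble::tibble(sf = spatial_frequency(image, scale),
                 ag = average_gradient(image, scale),
                 scale = scale)
}

#' Classification report (macro-averaged, in percent)
#'
#' Macro-averaged precision, recall and F1 (unweighted class means; a class
#' with no predictions contributes precision and F1 of 0) and overall
#' accuracy, as percentages rounded to one decimal. Classes are taken from
#' `y_true` (plus `class_names` if given).
#'
#' @param y_true,y_pred vectors of equal length (factors, characters or
#'   integers).
#' @param class_names optional class universe.
#' @return a `classification_report` with fields `f1`, `recall`, `precision`,
#'   `accuracy`, `per_class` (tibble) and `confusion` (matrix).
#' @export
classification_report <- function(y_true, y_pred, class_names = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (length(y_true) == 0L) stop("empty evaluation set")
  lev <- if (is.null(class_names))
    sort(unique(as.character(y_true))) else as.character(class_names)
  if (length(lev) < 2L) stop("need at least 2 classes in y_true")
  yt <- factor(as.character(y_true), levels = lev)
  yp <- factor(as.character(y_pred), levels = lev)
  if (anyNA(yt)) stop("y_true contains labels outside class_names")
  if (anyNA(yp)) stop("y_pred contains labels outside the class universe")
  conf <- table(true = yt, pred = yp)
  conf <- matrix(as.integer(conf), length(lev), length(lev),
                 dimnames = list(true = lev, pred = lev))
  tp <- unname(diag(conf))
  pred_n <- unname(colSums(conf))
  true_n <- unname(rowSums(conf))
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- tibble::tibble(class = lev,
                              precision = 100 * prec, recall = 100 * rec,
                              f1 = 100 * f1, support = as.integer(true_n))
  structure(list(f1 = round(100 * mean(f1), 1),
                 recall = round(100 * mean(rec), 1),
                 precision = round(100 * mean(prec), 1),
                 accuracy = round(100 * sum(tp) / sum(conf), 1),
                 per_class = per_class, confusion = conf),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> F1 %.1f | Rec %.1f | Pre %.1f | Acc %.1f (n=%d)\n",
    x$f1, x$recall, x$precision, x$accuracy, sum(x$confusion)))
  invisible(x)
}

#' Tidy a classification report into per-class rows
#' @param x a `classification_report`.
#' @param ... unused.
#' @return tibble with one row per class.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' One-row summary of a classification report
#' @param x a `classification_report`.
#' @param ... unused.
#' @return one-row tibble with `f1`, `recall`, `precision`, `accuracy`, `n`.
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(f1 = x$f1, recall = x$recall, precision = x$precision,
                 accuracy = x$accuracy, n = sum(x$confusion))
}

#' Write a classification report to CSV (per-class) and JSON (summary)
#' @param report a `classification_report`.
#' @param path_prefix files `<prefix>_per_class.csv` and `<prefix>.json` are
#'   written.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, path_prefix) {
  utils::write.csv(report$per_class,
                   paste0(path_prefix, "_per_class.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(f1 = report$f1, recall = report$recall,
         precision = report$precision, accuracy = report$accuracy,
         confusion = report$confusion),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path_prefix, ".json"))
}
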