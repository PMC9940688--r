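# Key-region extraction: threshold the importance map, keep the pixels at or
# above the threshold and mask everything else to black.  The masked image --
# only the evidence the models actually used -- is what the SVM stage sees.

#' Threshold an importance map into a binary mask
#'
#' A pixel is kept iff its normalized importance weight is `>= tau`.
#'
#' @param map an [importance_map()] or numeric matrix in `[0, 1]`.
#' @param tau threshold in `[0, 1]`.
#' @return logical matrix.
#' @export
threshold_mask <- function(map, tau = 0.5) {
  if (length(tau) != 1L || !is.finite(tau) || tau < 0 || tau > 1)
    stop("tau must be a single value in [0, 1]")
  v <- .map_values(map)
  v >= tau
}

#' Mask an image to its key region
#'
#' Zeroes all three channels wherever the mask is off. An empty mask is legal
#' (a degenerate all-suppressed map) and yields an all-black image with a
#' warning, so batch pipelines never crash on degenerate CAMs.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask logical/0-1 `H x W` matrix.
#' @param tau the threshold that produced the mask (metadata).
#' @return a `key_region_image` with fields `image`, `mask`, `tau`,
#'   `kept_fraction`.
#' @export
apply_mask <- function(image, mask, tau = NA_real_) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be an H x W x 3 array")
  if (!identical(d[1:2], dim(mask)[1:2]))
    stop("image/mask shape mismatch: ", paste(d[1:2], collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  m <- mask > 0.5
  kept <- mean(m)
  if (kept == 0) warning("empty key-region mask: output image is all black")
  out <- image * array(rep(as.numeric(m), 3L), d)
  structure(list(image = out, mask = m, tau = tau, kept_fraction = kept),
            class = "key_region_image")
}

#' @export
print.key_region_image <- function(x, ...) {
  cat(sprintf("<key_region_image> %s, tau=%s, kept %.1f%%\n",
              paste(dim(x$image), collapse = "x"),
              format(x$tau), 100 * x$kept_fraction))
  invisible(x)
}

#' Extract a key region from an image and an importance map
#'
#' Convenience composition of [threshold_mask()] and [apply_mask()].
#'
#' @inheritParams apply_mask
#' @inheritParams threshold_mask
#' @return a `key_region_image`.
#' @export
extract_key_region <- function(image, map, tau = 0.5) {
  apply_mask(image, threshold_mask(map, tau), tau = tau)
}

#' Flatten a key-region image into an SVM feature vector
#'
#' The masked image is bilinearly resized to `side x side` and flattened
#' channel-last, row-major (pixels in reading order, each pixel's R, G, B
#' contiguous). Deterministic.
#'
#' @param kr a `key_region_image` (or plain `H x W x 3` array).
#' @param side output edge S in pixels (>= 8).
#' @return numeric vector of length `3 * side^2`.
#' @export
feature_vector <- function(kr, side = 64L) {
  side <- as.integer(side)
  if (side < 8L) stop("side must be at least 8")
  img <- if (inherits(kr, "key_region_image")) kr$image else kr
  r <- bilinear_resize(img, side, side)
  as.vector(aperm(r, c(3L, 2L, 1L)))
}
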