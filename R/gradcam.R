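# Grad-CAM: channel weights by global average pooling of the class-score
# gradients, a ReLU-ed weighted sum of the activation channels, bilinear
# upsampling to image resolution and a per-map min-max rescale.  The resulting
# importance map -- per-pixel neuron-importance weights in [0, 1] -- is the
# currency every later stage (fusion, thresholding, masking) trades in.

#' Construct an importance map
#'
#' @param values numeric `H x W` matrix with entries in `[0, 1]`.
#' @param source `"cnn"`, `"vit"`, `"swin"` or `"fused"`.
#' @param image_id identifier of the image the map is aligned to.
#' @param target_class class index the map explains.
#' @return an `importance_map` object.
#' @export
importance_map <- function(values, source = c("cnn", "vit", "swin", "fused"),
                           image_id = NA_character_, target_class = NA_integer_) {
  source <- match.arg(source)
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values) || min(values) < -1e-9 || max(values) > 1 + 1e-9)
    stop("importance map values must lie in [0, 1]")
  values[values < 0] <- 0
  values[values > 1] <- 1
  structure(list(values = values, source = source,
                 image_id = as.character(image_id),
                 target_class = as.integer(target_class)),
            class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat("<importance_map>", x$source, paste(dim(x$values), collapse = "x"),
      sprintf(" range [%.3f, %.3f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Grad-CAM channel weights
#'
#' The neuron-importance weight of each activation channel: the spatial mean
#' (global average pooling) of the class-score gradients over that channel.
#'
#' @param out a `backbone_output` from [forward_with_grads()].
#' @return numeric vector, one weight per channel.
#' @export
channel_weights <- function(out) {
  stopifnot(inherits(out, "backbone_output"),
            identical(dim(out$activations), dim(out$gradients)))
  apply(out$gradients, 1L, mean)
}

#' Compute a Grad-CAM importance map
#'
#' `ReLU(sum_k alpha_k A_k)` at the target layer's native resolution, bilinearly
#' resampled to `out_size` and min-max rescaled to `[0, 1]`.  An all-zero raw
#' map (all class evidence suppressed by the ReLU) stays all zeros.
#'
#' @param out a `backbone_output`.
#' @param out_size integer `(H, W)` of the output map (usually the image size).
#' @param source source tag for the resulting map.
#' @param image_id identifier passed through to the map.
#' @return an [importance_map()].
#' @export
compute_cam <- function(out, out_size,
                        source = c("cnn", "vit", "swin", "fused"),
                        image_id = NA_character_) {
  source <- match.arg(source)
  stopifnot(length(out_size) == 2L, all(out_size >= 1))
  w <- channel_weights(out)
  d <- dim(out$activations)
  acts <- matrix(out$activations, d[1L], d[2L] * d[3L])
  raw <- matrix(colSums(acts * w), d[2L], d[3L])
  raw <- relu(raw)
  up <- bilinear_resize(raw, out_size[1L], out_size[2L])
  importance_map(minmax_norm(up), source = source, image_id = image_id,
                 target_class = out$target_class)
}

#' Intersection over union of two binary masks
#'
#' Defined as 1 when both masks are empty.
#'
#' @param a,b logical or 0/1 matrices of identical shape.
#' @return a number in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  a <- a > 0.5
  b <- b > 0.5
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Persist / load an importance map
#'
#' The map is written as a 16-bit single-channel TIFF
#' (`value = round(65535 * w) / 65535`, lossless at that quantization)
#' plus a JSON sidecar `<path>.json` with `image_id`, `source`,
#' `target_class` and the value range.
#'
#' @param map an [importance_map()].
#' @param path output path (`.tif`).
#' @return `read_importance_map` returns an `importance_map`.
#' @export
write_importance_map <- function(map, path) {
  stopifnot(inherits(map, "importance_map"))
  q <- round(map$values * 65535) / 65535
  tiff::writeTIFF(q, path, bits.per.sample = 16L)
  side <- list(image_id = map$image_id, source = map$source,
               target_class = map$target_class,
               dtype_range = c(0, 1), encoding = "uint16")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_importance_map
#' @export
read_importance_map <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(source = "fused", image_id = NA, target_class = NA)
  importance_map(v, source = meta$source, image_id = meta$image_id,
                 target_class = if (is.null(meta$target_class) ||
                                    is.na(meta$target_class)) NA_integer_
                                else meta$target_class)
}
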