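# Calibrated augmentation suite: seven methods, each applied independently
# with its own probability and parameters drawn uniformly within fixed limits.
# Defaults (limits and probabilities):
#   HF       horizontal flip                          p = 0.5
#   BC       brightness (-0.3, 0.3), contrast (-0.3, 0.3)   p = 0.4
#   Shift    (-0.65, 0.65) fraction of each dimension       p = 0.4
#   Scale    (-0.1, 0.1)                                    p = 0.3
#   Rotate   (-45, 45) degrees                              p = 0.4
#   GB       Gaussian blur, odd kernel in (3, 7)            p = 0.5
#   Sharpen  alpha (0.2, 0.5), lightness (0.5, 1.0)         p = 0.3
# Methods are applied in this fixed order; geometric ops use reflection
# padding and bilinear interpolation; outputs are clipped to [0, 1].

#' Default augmentation specifications
#'
#' @return a tibble with columns `method`, `limits` (named list per method)
#'   and `probability`.
#' @export
augmentation_specs <- function() {
  tibble::tibble(
    method = c("HF", "BC", "Shift", "Scale", "Rotate", "GB", "Sharpen"),
    limits = list(
      list(),
      list(brightness = c(-0.3, 0.3), contrast = c(-0.3, 0.3)),
      list(shift = c(-0.65, 0.65)),
      list(scale = c(-0.1, 0.1)),
      list(angle = c(-45, 45)),
      list(kernel = c(3, 7)),
      list(alpha = c(0.2, 0.5), lightness = c(0.5, 1.0))
    ),
    probability = c(0.5, 0.4, 0.4, 0.3, 0.4, 0.5, 0.3)
  )
}

#' Sample an augmentation plan
#'
#' Each method is included independently with its probability; its parameters
#' are drawn uniformly within their limits (the blur kernel as an odd integer
#' in its range; the shift is drawn per axis). Deterministic given the seed.
#'
#' @param specs a specification tibble as from [augmentation_specs()].
#' @param rng_seed integer seed.
#' @return an `augmentation_plan`: ordered list of `list(method, params)`.
#' @export
sample_plan <- function(specs = augmentation_specs(), rng_seed = 1L) {
  if (any(specs$probability < 0 | specs$probability > 1))
    stop("probabilities must lie in [0, 1]")
  plan <- with_seed(rng_seed, {
    steps <- list()
    for (i in seq_len(nrow(specs))) {
      if (stats::runif(1) >= specs$probability[i]) next
      lim <- specs$limits[[i]]
      m <- specs$method[i]
      params <- switch(
        m,
        HF = list(),
        BC = list(brightness = stats::runif(1, lim$brightness[1], lim$brightness[2]),
                  contrast = stats::runif(1, lim$contrast[1], lim$contrast[2])),
        Shift = list(dy = stats::runif(1, lim$shift[1], lim$shift[2]),
                     dx = stats::runif(1, lim$shift[1], lim$shift[2])),
        Scale = list(scale = stats::runif(1, lim$scale[1], lim$scale[2])),
        Rotate = list(angle = stats::runif(1, lim$angle[1], lim$angle[2])),
        GB = list(kernel = sample(seq(lim$kernel[1], lim$kernel[2], by = 2), 1L)),
        Sharpen = list(alpha = stats::runif(1, lim$alpha[1], lim$alpha[2]),
                       lightness = stats::runif(1, lim$lightness[1], lim$lightness[2])),
        stop("unknown augmentation method: ", m)
      )
      steps[[length(steps) + 1L]] <- list(method = m, params = params)
    }
    steps
  })
  structure(plan, class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<augmentation_plan> (empty)\n")
    return(invisible(x))
  }
  for (s in x)
    cat("<augmentation_plan step>", s$method,
        if (length(s$params)) paste0("(", paste(names(s$params),
          signif(unlist(s$params), 3), sep = "=", collapse = ", "), ")") else "",
        "\n")
  invisible(x)
}

.aug_hf <- function(img) img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]

.aug_bc <- function(img, brightness, contrast)
  clip01((img - 0.5) * (1 + contrast) + 0.5 + brightness)

.aug_sharpen <- function(img, alpha, lightness) {
  blur <- gaussian_blur(img, 3L)
  sharpened <- img + lightness * (img - blur)
  clip01((1 - alpha) * img + alpha * sharpened)
}

#' Apply an augmentation plan to an image
#'
#' Steps are applied in plan order (the fixed method order of
#' [augmentation_specs()] when the plan came from [sample_plan()]). The shape
#' is preserved and the output is clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param plan an `augmentation_plan` (possibly empty).
#' @return augmented image array.
#' @export
apply_plan <- function(image, plan) {
  stopifnot(length(dim(image)) == 3L)
  for (s in plan) {
    p <- s$params
    image <- switch(s$method,
      HF = .aug_hf(image),
      BC = .aug_bc(image, p$brightness, p$contrast),
      Shift = warp_affine(image, shift_frac = c(p$dy, p$dx)),
      Scale = warp_affine(image, zoom = 1 + p$scale),
      Rotate = warp_affine(image, angle = p$angle),
      GB = gaussian_blur(image, as.integer(p$kernel)),
      Sharpen = .aug_sharpen(image, p$alpha, p$lightness),
      stop("unknown augmentation method: ", s$method))
  }
  clip01(image)
}

#' Top up every class of a dataset to a target size by augmentation
#'
#' Original images are always retained; deficient classes are topped up by
#' augmenting uniformly sampled source images of the same class. Each
#' augmented entry records its plan (JSON) for reproducibility. Deterministic
#' given the seed.
#'
#' @param manifest tibble with at least `path` and `label` columns.
#' @param target_per_class desired image count per class.
#' @param rng_seed integer seed.
#' @param dir output directory for augmented images (default: alongside the
#'   sources in an `augmented/` subdirectory).
#' @param specs augmentation specifications.
#' @return the augmented manifest tibble with columns `path`, `label`,
#'   `origin` (`"original"`/`"augmented"`) and `plan` (JSON or `NA`).
#' @export
balance_dataset <- function(manifest, target_per_class, rng_seed = 1L,
                            dir = NULL, specs = augmentation_specs()) {
  stopifnot(all(c("path", "label") %in% names(manifest)))
  counts <- table(manifest$label)
  if (nrow(manifest) == 0L || any(counts < 1L))
    stop("every class must have at least one image")
  if (is.null(dir)) dir <- file.path(dirname(manifest$path[1L]), "augmented")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- tibble::tibble(path = manifest$path, label = manifest$label,
                        origin = "original", plan = NA_character_)
  new_rows <- list()
  labels <- sort(unique(as.character(manifest$label)))
  for (li in seq_along(labels)) {
    lab <- labels[li]
    src <- manifest$path[manifest$label == lab]
    deficit <- target_per_class - length(src)
    if (deficit <= 0L) next
    pick <- with_seed(rng_seed * 131L + li, sample.int(length(src), deficit,
                                                       replace = TRUE))
    for (j in seq_len(deficit)) {
      step_seed <- (rng_seed * 7919L + li * 613L + j) %% 2147483647L
      plan <- sample_plan(specs, rng_seed = step_seed)
      img <- load_image(src[pick[j]])
      aug <- apply_plan(img, plan)
      pth <- file.path(dir, sprintf("aug_%s_%04d.png", lab, j))
      png::writePNG(clip01(aug), pth)
      new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
        path = pth, label = lab, origin = "augmented",
        plan = plan_to_json(plan))
    }
  }
  dplyr::bind_rows(out, new_rows)
}

#' Serialize an augmentation plan to JSON (and back)
#' @param plan an `augmentation_plan`.
#' @return `plan_to_json` a JSON string; `plan_from_json` a plan.
#' @export
plan_to_json <- function(plan) {
  as.character(jsonlite::toJSON(lapply(plan, function(s)
    list(method = s$method, params = s$params)), auto_unbox = TRUE,
    digits = NA))
}

#' @rdname plan_to_json
#' @param json JSON string.
#' @export
plan_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(lapply(lst, function(s)
    list(method = s$method, params = lapply(s$params, as.numeric))),
    class = "augmentation_plan")
}

#' Read an RGB image from PNG or JPEG as an `H x W x 3` array in `[0, 1]`
#' @param path image path (`.png`, `.jpg`/`.jpeg`).
#' @return numeric array; grayscale is replicated to 3 channels, alpha dropped.
#' @export
load_image <- function(path) {
  img <- if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the jpeg package")
    jpeg::readJPEG(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}
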