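# End-to-end orchestration: per-image importance maps (precomputed view maps
# or Grad-CAM from the three backbones) -> attention-selection fusion ->
# key-region masking -> feature vectors -> stratified split -> SVM ->
# classification report.  Every stage is seed-controlled; re-running a config
# reproduces the report byte-exactly.

#' Pipeline configuration
#'
#' @param manifest a manifest tibble (or path to `manifest.csv`) with `path`,
#'   `label` and -- in precomputed mode -- `map_cnn`, `map_vit`, `map_swin`
#'   columns.
#' @param mode `"precomputed"` (read per-view maps from the manifest) or
#'   `"backbone"` (compute Grad-CAMs with the three backbones).
#' @param backbones named list of three [backbone_spec()]s (`cnn`, `vit`,
#'   `swin`); required in backbone mode.
#' @param fusion a [fusion_config()].
#' @param fusion_mode `"network"` (full extract/select/reconstruct) or
#'   `"map"` (selection rule on the raw maps).
#' @param views character: the views to use -- a subset of
#'   `c("cnn", "vit", "swin")`. One name uses that view's map directly;
#'   several are fused.
#' @param tau key-region threshold in `[0, 1]`.
#' @param feature_side resize edge for the SVM feature vectors.
#' @param svm an [svm_config()].
#' @param split a [split_spec()].
#' @param out_dir optional artifact directory (report JSON + config sidecar).
#' @param verbose log stage progress.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(manifest, mode = c("precomputed", "backbone"),
                            backbones = NULL, fusion = fusion_config(),
                            fusion_mode = c("network", "map"),
                            views = c("cnn", "vit", "swin"),
                            tau = 0.5, feature_side = 64L,
                            svm = svm_config(), split = split_spec(),
                            out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  fusion_mode <- match.arg(fusion_mode)
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read_manifest(manifest)
  stopifnot(all(c("path", "label") %in% names(manifest)))
  views <- match.arg(views, c("cnn", "vit", "swin"), several.ok = TRUE)
  if (length(views) == 0L) stop("at least one view is required")
  if (mode == "backbone" &&
      !(is.list(backbones) && all(c("cnn", "vit", "swin") %in% names(backbones))))
    stop("backbone mode needs a named list of cnn/vit/swin backbone specs")
  structure(list(manifest = manifest, mode = mode, backbones = backbones,
                 fusion = fusion, fusion_mode = fusion_mode, views = views,
                 tau = tau, feature_side = as.integer(feature_side),
                 svm = svm, split = split, out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.log_stage <- function(cfg, ...) if (isTRUE(cfg$verbose)) message("[camfuse] ", ...)

.config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$manifest <- list(n = nrow(cfg$manifest),
                     files = as.character(cfg$manifest$path))
  x$out_dir <- NULL
  x$verbose <- NULL
  rlang::hash(x)
}

# Per-image view maps as plain matrices, named by source.
.image_maps <- function(cfg, row, models = NULL) {
  if (cfg$mode == "precomputed") {
    cols <- paste0("map_", c("cnn", "vit", "swin"))
    if (!all(cols %in% names(cfg$manifest)))
      stop("precomputed mode needs map_cnn/map_vit/map_swin manifest columns")
    out <- lapply(cols, function(cl) read_importance_map(row[[cl]])$values)
    names(out) <- c("cnn", "vit", "swin")
    return(out)
  }
  img <- load_image(row$path)
  out <- lapply(models, function(m) {
    bo <- forward_with_grads(m, img, "argmax")
    compute_cam(bo, dim(img)[1:2], source = m$spec$family,
                image_id = row$image_id)$values
  })
  names(out) <- names(models)
  out
}

# Fused (or single-view) map for one image from its named view maps.
.select_map <- function(maps, views, cfg) {
  if (length(views) == 1L) return(maps[[views]])
  .fuse_values(unname(maps[views]), cfg$fusion, cfg$fusion_mode)
}

# Feature matrix + labels for one view set. `map_cache` lets the ablation
# path reuse loaded maps across subsets.
.collect_features <- function(cfg, views, map_cache = NULL) {
  n <- nrow(cfg$manifest)
  models <- NULL
  if (cfg$mode == "backbone")
    models <- lapply(cfg$backbones, build_backbone)
  x <- NULL
  kept <- numeric(n)
  for (i in seq_len(n)) {
    row <- cfg$manifest[i, ]
    maps <- if (!is.null(map_cache)) map_cache[[i]]
            else .image_maps(cfg, row, models)
    fmap <- .select_map(maps, views, cfg)
    img <- load_image(row$path)
    kr <- suppressWarnings(extract_key_region(img, fmap, cfg$tau))
    v <- feature_vector(kr, cfg$feature_side)
    if (is.null(x)) x <- matrix(0, n, length(v))
    x[i, ] <- v
    kept[i] <- kr$kept_fraction
  }
  list(x = x, y = as.character(cfg$manifest$label), kept = kept)
}

#' Run the full pipeline
#'
#' Stages: per-view importance maps, fusion over `cfg$views`, thresholded
#' key-region masking, feature extraction, stratified split, SVM fit and
#' held-out evaluation. With `out_dir` set, the report and a config-hash
#' sidecar are written (no timestamps, so reruns are byte-identical).
#'
#' @param cfg a [pipeline_config()].
#' @return a `camfuse_run`: `report` (a [classification_report()]), `fit`,
#'   `split`, `kept_fraction`, `views`, `config_hash`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- .config_hash(cfg)
  .log_stage(cfg, "features: ", nrow(cfg$manifest), " images, views = ",
             paste(cfg$views, collapse = "+"), ", hash = ", hash)
  fx <- .collect_features(cfg, cfg$views)
  .log_stage(cfg, "split: train fraction ", cfg$split$train_fraction,
             ", seed ", cfg$split$seed)
  idx <- split_indices(fx$y, cfg$split)
  .log_stage(cfg, "svm: ", length(idx$train), " train / ",
             length(idx$test), " test")
  fit <- svm_fit(fx$x[idx$train, , drop = FALSE], fx$y[idx$train], cfg$svm)
  report <- svm_evaluate(fit, fx$x[idx$test, , drop = FALSE], fx$y[idx$test])
  out <- structure(list(report = report, fit = fit, split = idx,
                        kept_fraction = fx$kept, views = cfg$views,
                        config_hash = hash),
                   class = "camfuse_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(cfg$out_dir, "report"))
    jsonlite::write_json(list(config_hash = hash,
                              views = cfg$views, tau = cfg$tau,
                              fusion_mode = cfg$fusion_mode),
                         file.path(cfg$out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.camfuse_run <- function(x, ...) {
  cat("<camfuse_run> views:", paste(x$views, collapse = "+"), "\n  ")
  print(x$report)
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x a `camfuse_run`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance camfuse_run
#' @export
glance.camfuse_run <- function(x, ...) {
  dplyr::mutate(glance(x$report),
                views = paste(x$views, collapse = "+"),
                mean_kept = mean(x$kept_fraction),
                config_hash = x$config_hash, .before = 1L)
}

#' View-subset ablation
#'
#' For each requested view subset, fuses only those views (the selection rule
#' generalizes to any subset; a singleton uses its map directly), extracts key
#' regions, trains and evaluates the SVM under one shared split, and tabulates
#' the reports. Per-image view maps (and, in network mode, their conv feature
#' stacks) are computed once and shared across subsets.
#'
#' @param cfg a [pipeline_config()] (its `views` field is ignored).
#' @param subsets list of character vectors, e.g.
#'   `list("cnn", c("cnn", "vit"), c("cnn", "vit", "swin"))`.
#' @param path optional CSV output path for the summary table.
#' @return tibble: one row per subset with the macro metrics, plus a `report`
#'   list-column.
#' @export
ablation <- function(cfg, subsets, path = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (length(subsets) == 0L) stop("empty subset list")
  subsets <- lapply(subsets, function(s)
    match.arg(s, c("cnn", "vit", "swin"), several.ok = TRUE))
  n <- nrow(cfg$manifest)
  models <- if (cfg$mode == "backbone")
    lapply(cfg$backbones, build_backbone) else NULL
  multi <- Filter(function(s) length(s) > 1L, subsets)
  need_stacks <- cfg$fusion_mode == "network" && length(multi) > 0L
  feats <- vector("list", length(subsets))
  y <- as.character(cfg$manifest$label)
  .log_stage(cfg, "ablation: ", n, " images x ", length(subsets), " subsets")
  for (i in seq_len(n)) {
    row <- cfg$manifest[i, ]
    maps <- .image_maps(cfg, row, models)
    img <- load_image(row$path)
    stacks <- if (need_stacks)
      lapply(maps, .extract_stack, cfg = cfg$fusion) else NULL
    for (s in seq_along(subsets)) {
      vs <- subsets[[s]]
      fmap <- if (length(vs) == 1L) maps[[vs]]
              else if (cfg$fusion_mode == "map")
                .fuse_values(unname(maps[vs]), cfg$fusion, "map")
              else .fuse_from_stacks(unname(stacks[vs]), cfg$fusion)
      kr <- suppressWarnings(extract_key_region(img, fmap, cfg$tau))
      v <- feature_vector(kr, cfg$feature_side)
      if (is.null(feats[[s]])) feats[[s]] <- matrix(0, n, length(v))
      feats[[s]][i, ] <- v
    }
  }
  rows <- vector("list", length(subsets))
  idx <- split_indices(y, cfg$split)
  for (s in seq_along(subsets)) {
    vs <- subsets[[s]]
    .log_stage(cfg, "ablation subset: ", paste(vs, collapse = "+"))
    fit <- svm_fit(feats[[s]][idx$train, , drop = FALSE], y[idx$train],
                   cfg$svm)
    rep <- svm_evaluate(fit, feats[[s]][idx$test, , drop = FALSE],
                        y[idx$test])
    rows[[s]] <- dplyr::mutate(glance(rep),
                               subset = paste(vs, collapse = "+"),
                               n_views = length(vs), .before = 1L)
    rows[[s]]$report <- list(rep)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path))
    utils::write.csv(dplyr::select(out, -"report"), path, row.names = FALSE)
  out
}

#' Robustness of thresholded maps across paired original/perturbed images
#'
#' For each pair, reports the IoU between the thresholded importance maps of
#' the two members, per view and for the fused map.
#'
#' @param pairs pairs as from [make_robustness_pairs()]: each element has
#'   `original$views` and `augmented$views` (named lists of map matrices in a
#'   common frame).
#' @param fusion a [fusion_config()].
#' @param fusion_mode `"network"` or `"map"`.
#' @param tau threshold in `[0, 1]`.
#' @param path optional CSV output path.
#' @return tibble with one row per pair: `iou_cnn`, `iou_vit`, `iou_swin`,
#'   `mean_single`, `iou_fused`.
#' @export
robustness_check <- function(pairs, fusion = fusion_config(),
                             fusion_mode = c("network", "map"), tau = 0.5,
                             path = NULL) {
  fusion_mode <- match.arg(fusion_mode)
  if (length(pairs) == 0L) stop("empty pair list")
  bad <- !vapply(pairs, function(p)
    is.list(p$original$views) && is.list(p$augmented$views) &&
      identical(names(p$original$views), names(p$augmented$views)),
    logical(1L))
  if (any(bad)) stop("unpaired or mismatched inputs at pair ", which(bad)[1L])
  rows <- vector("list", length(pairs))
  for (p in seq_along(pairs)) {
    vo <- pairs[[p]]$original$views
    va <- pairs[[p]]$augmented$views
    singles <- vapply(names(vo), function(s)
      iou(threshold_mask(vo[[s]], tau), threshold_mask(va[[s]], tau)),
      numeric(1L))
    fo <- .fuse_values(unname(vo), fusion, fusion_mode)
    fa <- .fuse_values(unname(va), fusion, fusion_mode)
    fused <- iou(threshold_mask(fo, tau), threshold_mask(fa, tau))
    rows[[p]] <- tibble::tibble(pair = p,
                                iou_cnn = singles[["cnn"]],
                                iou_vit = singles[["vit"]],
                                iou_swin = singles[["swin"]],
                                mean_single = mean(singles),
                                iou_fused = fused)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `fusion`, `svm`
#' and `split` are nested maps passed to their constructors; `manifest` is a
#' path to a manifest CSV.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list(manifest = lst$manifest)
  for (nm in c("mode", "fusion_mode", "views", "tau", "feature_side",
               "out_dir", "verbose"))
    if (!is.null(lst[[nm]])) args[[nm]] <- lst[[nm]]
  if (!is.null(lst$fusion)) args$fusion <- do.call(fusion_config, lst$fusion)
  if (!is.null(lst$svm)) args$svm <- do.call(svm_config, lst$svm)
  if (!is.null(lst$split)) args$split <- do.call(split_spec, lst$split)
  if (!is.null(lst$backbones))
    args$backbones <- lapply(lst$backbones, function(b)
      do.call(backbone_spec, b))
  do.call(pipeline_config, args)
}
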