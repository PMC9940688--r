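# Attention-selection fusion of per-view importance maps, built on a small
# four-layer image-fusion convolutional network (extract -> select ->
# reconstruct).  CONV1/CONV2 extract per-view feature stacks with weights
# shared across views; the selection rule combines, per channel and pixel, the
# consensus (elementwise minimum across views, weighted w0) with the
# complement (union minus intersection, i.e. max - min, weighted w1), followed
# by an optional rank-1 "eigen" smoothing of the channel stack; CONV3/CONV4
# tune and reconstruct a 3-channel output whose luminance is the fused map.
#
# Untrained kernels are drawn nonnegative and normalized to unit sum per
# output channel, so the untrained network behaves as an ensemble of local
# averaging filters: features remain faithful smoothed copies of the maps and
# the selection algebra keeps its intended meaning.  Trained fusion weights
# can be imported with load_fusion_weights().

#' Fusion configuration
#'
#' @param w0 weight of the consensus (intersection) component; `w0 >= w1 >= 0`.
#' @param w1 weight of the complement (union minus intersection) component.
#' @param eigen logical; apply rank-1 eigen smoothing to the fused channel
#'   stack.
#' @param conv_channels integer length-3: output channels of CONV1..CONV3.
#' @param n_inputs number of fused views; fixed at 3 (one CAM per backbone).
#' @param seed seed for the network weights.
#' @return a `fusion_config` object.
#' @export
fusion_config <- function(w0 = 1, w1 = 0.5, eigen = TRUE,
                          conv_channels = c(64L, 64L, 64L),
                          n_inputs = 3L, seed = 1L) {
  if (!(w0 >= w1 && w1 >= 0))
    stop("fusion weights must satisfy w0 >= w1 >= 0")
  if (n_inputs != 3L) stop("n_inputs is fixed at 3")
  stopifnot(length(conv_channels) == 3L, all(conv_channels >= 1L))
  structure(list(w0 = w0, w1 = w1, eigen = isTRUE(eigen),
                 conv_channels = as.integer(conv_channels),
                 out_channels = 3L, n_inputs = 3L, seed = as.integer(seed)),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat(sprintf("<fusion_config> w0=%g w1=%g eigen=%s conv=%s seed=%d\n",
              x$w0, x$w1, x$eigen, paste(x$conv_channels, collapse = "/"),
              x$seed))
  invisible(x)
}

.smooth_kernel <- function(kh, kw, cin, cout) {
  w <- abs(stats::rnorm(kh * kw * cin * cout))
  w <- array(w, c(kh, kw, cin, cout))
  for (o in seq_len(cout)) w[, , , o] <- w[, , , o] / sum(w[, , , o])
  w
}

# Network weights for a config (cached per config hash so repeated fusions of
# the same configuration do not re-seed).
fusion_weights <- function(cfg) {
  key <- paste0("fusnet_", cfg$seed, "_", paste(cfg$conv_channels, collapse = "_"))
  hit <- .camfuse_cache[[key]]
  if (!is.null(hit)) return(hit)
  cc <- cfg$conv_channels
  w <- with_seed(cfg$seed, list(
    conv1_w = .smooth_kernel(7L, 7L, 3L, cc[1L]), conv1_b = rep(0, cc[1L]),
    conv2_w = .smooth_kernel(3L, 3L, cc[1L], cc[2L]), conv2_b = rep(0, cc[2L]),
    conv3_w = .smooth_kernel(3L, 3L, cc[2L], cc[3L]), conv3_b = rep(0, cc[3L]),
    conv4_w = .smooth_kernel(1L, 1L, cc[3L], 3L), conv4_b = rep(0, 3L)))
  .camfuse_cache[[key]] <- w
  w
}

#' Import fusion-network weights from file
#'
#' @param cfg a [fusion_config()].
#' @param path RDS archive holding a named list `conv1_w`, `conv1_b`, ...
#' @return invisibly, the config (weights are cached for this config).
#' @export
load_fusion_weights <- function(cfg, path) {
  w <- readRDS(path)
  need <- c("conv1_w", "conv1_b", "conv2_w", "conv2_b",
            "conv3_w", "conv3_b", "conv4_w", "conv4_b")
  if (!all(need %in% names(w))) stop("weights file missing fusion layers")
  key <- paste0("fusnet_", cfg$seed, "_", paste(cfg$conv_channels, collapse = "_"))
  .camfuse_cache[[key]] <- w[need]
  invisible(cfg)
}

.map_values <- function(m) if (inherits(m, "importance_map")) m$values else m

# CONV1 -> ReLU -> CONV2 -> ReLU for one map (weights shared across views),
# channels last (u, v, K).
.extract_one <- function(vals, w) {
  x <- array(rep(vals, 3L), c(dim(vals), 3L))
  x <- relu(conv2d(x, w$conv1_w, w$conv1_b, padding = 3L))
  relu(conv2d(x, w$conv2_w, w$conv2_b, padding = 1L))
}

.normalize_stack <- function(x, eps = 1e-12) {
  # per-channel min-max over the spatial axes, in one vectorized pass;
  # constant channels become all-one (positive) or all-zero
  d <- dim(x)
  uv <- d[1L] * d[2L]
  dim(x) <- c(uv, d[3L])
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  flat <- rng < eps
  scale <- ifelse(flat, 0, 1 / ifelse(flat, 1, rng))
  offset <- ifelse(flat, ifelse(hi > eps, 1, 0), -lo * scale)
  x <- x * rep(scale, each = uv) + rep(offset, each = uv)
  dim(x) <- d
  x
}

#' Extract per-view attention feature stacks
#'
#' Each single-channel map is replicated to 3 channels and passed through
#' CONV1 (7x7) and CONV2 (3x3) with weights shared across the views; the
#' outputs are per-channel min-max normalized so they can serve as the
#' per-view importance weights of the selection rule.
#'
#' @param cams list of exactly 3 [importance_map()]s (or matrices) sharing one
#'   shape.
#' @param cfg a [fusion_config()].
#' @return a `feature_stack`: array `(n_inputs, K, u, v)` with `normalized = TRUE`.
#' @export
extract_features <- function(cams, cfg = fusion_config()) {
  if (length(cams) != 3L) stop("exactly 3 importance maps are required")
  vals <- lapply(cams, .map_values)
  d1 <- dim(vals[[1L]])
  if (!all(vapply(vals, function(v) identical(dim(v), d1), logical(1L))))
    stop("importance maps must share the same shape")
  w <- fusion_weights(cfg)
  K <- cfg$conv_channels[2L]
  maps <- array(0, c(3L, K, d1[1L], d1[2L]))
  for (i in 1:3) {
    f <- .normalize_stack(.extract_one(vals[[i]], w))
    maps[i, , , ] <- aperm(f, c(3L, 1L, 2L))
  }
  structure(list(maps = maps, normalized = TRUE), class = "feature_stack")
}

#' Attention-selection rule over a feature stack
#'
#' Per channel `k` and pixel: with `I = min_i alpha_i^k` (the consensus across
#' views) and `U = max_i alpha_i^k` (their union), the fused value is
#' `w0 * I + w1 * (U - I)`; optionally the fused channel stack is replaced by
#' its rank-1 eigen reconstruction to suppress noise. Output is clipped to
#' `[0, w0]`.
#'
#' @param stack a `feature_stack` (normalized), or an `(n, K, u, v)` array of
#'   values in `[0, 1]`.
#' @param cfg a [fusion_config()].
#' @return a `fused_stack` with `maps` of shape `(K, u, v)`.
#' @export
attention_rec <- function(stack, cfg = fusion_config()) {
  maps <- if (inherits(stack, "feature_stack")) {
    if (!isTRUE(stack$normalized)) stop("feature stack must be normalized")
    stack$maps
  } else stack
  d <- dim(maps)
  stopifnot(length(d) == 4L)
  if (min(maps) < -1e-9 || max(maps) > 1 + 1e-9)
    stop("attention_rec expects values in [0, 1]; normalize the stack first")
  n <- d[1L]
  I <- maps[1L, , , , drop = TRUE]
  U <- I
  if (n > 1L) for (i in 2:n) {
    mi <- maps[i, , , , drop = TRUE]
    I <- pmin(I, mi)
    U <- pmax(U, mi)
  }
  fused <- cfg$w0 * I + cfg$w1 * (U - I)
  dim(fused) <- d[-1L]
  if (cfg$eigen) fused <- eigen_smooth(fused)
  fused[fused < 0] <- 0
  fused[fused > cfg$w0] <- cfg$w0
  structure(list(maps = fused), class = "fused_stack")
}

#' Rank-1 eigen smoothing of a channel stack
#'
#' Flattens a `(K, u, v)` stack to a `K x (u*v)` matrix, replaces it by its
#' leading singular-value reconstruction `sigma_1 u_1 v_1'` (sign chosen so the
#' spatial component correlates nonnegatively with the channel-mean map),
#' clips negatives to zero and reshapes back.  Stacks of (nonnegative
#' multiples of) a single map are fixed points.
#'
#' @param stack `(K, u, v)` array.
#' @return smoothed array of the same shape.
#' @export
eigen_smooth <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 3L, d[1L] >= 1L)
  X <- stack
  dim(X) <- c(d[1L], d[2L] * d[3L])
  R <- .rank1_channels(t(X))
  R <- t(R)
  dim(R) <- d
  R
}

# Rank-1 reconstruction of an (n_pixels, K) matrix across its channel axis:
# the projection M u1 u1' onto the leading eigenvector u1 of the K x K
# cross-product -- algebraically sigma_1 u_1 v_1' of the SVD of M', computed
# without a full decomposition (and independent of the sign convention, since
# the spatial component sigma v_1 = M u_1 flips with u_1).  Negatives are
# clipped to zero.
.rank1_channels <- function(M) {
  if (ncol(M) == 1L) {
    R <- M
  } else {
    S <- crossprod(M)
    if (all(S == 0)) return(M)
    u1 <- eigen(S, symmetric = TRUE)$vectors[, 1L]
    R <- (M %*% u1) %*% t(u1)
  }
  R[R < 0] <- 0
  R
}

#' Reconstruct a fused 3-channel image from a fused stack
#'
#' CONV3 (3x3) tunes the selected features and CONV4 (1x1) maps them to a
#' 3-channel output, min-max normalized to `[0, 1]`.
#'
#' @param fused a `fused_stack` (or `(K, u, v)` array).
#' @param cfg a [fusion_config()]; `K` must equal `conv_channels[2]`.
#' @return `(3, u, v)` array in `[0, 1]`.
#' @export
reconstruct <- function(fused, cfg = fusion_config()) {
  maps <- if (inherits(fused, "fused_stack")) fused$maps else fused
  d <- dim(maps)
  stopifnot(length(d) == 3L, all(is.finite(maps)))
  w <- fusion_weights(cfg)
  x <- aperm(maps, c(2L, 3L, 1L))
  x <- relu(conv2d(x, w$conv3_w, w$conv3_b, padding = 1L))
  x <- conv2d(x, w$conv4_w, w$conv4_b, padding = 0L)
  aperm(minmax_norm(x), c(3L, 1L, 2L))
}

# Normalized channel-last (u, v, K) feature stack for one map -- the unit
# the ablation path caches per image and view.  Channel-last avoids any
# layout shuffle between the convolution stages.
.extract_stack <- function(vals, cfg) {
  w <- fusion_weights(cfg)
  .normalize_stack(.extract_one(vals, w))
}

# Selection + reconstruction from channel-last per-view stacks (any subset
# size >= 1).  Numerically identical to composing the public attention_rec()
# and reconstruct() on the channel-first layout.  rule = "average" replaces
# the selection step by the plain elementwise mean across views (the
# unmodified fusion-framework baseline the selection rule is compared
# against), keeping every other stage identical.
.fuse_from_stacks <- function(stacks, cfg, rule = "attention") {
  if (rule == "average") {
    fused <- Reduce(`+`, stacks) / length(stacks)
  } else {
    I <- stacks[[1L]]
    U <- I
    if (length(stacks) > 1L) for (i in 2:length(stacks)) {
      I <- pmin(I, stacks[[i]])
      U <- pmax(U, stacks[[i]])
    }
    fused <- cfg$w0 * I + cfg$w1 * (U - I)
  }
  d <- dim(fused)
  if (cfg$eigen) {
    dim(fused) <- c(d[1L] * d[2L], d[3L])
    fused <- .rank1_channels(fused)
    dim(fused) <- d
  }
  fused[fused < 0] <- 0
  fused[fused > cfg$w0] <- cfg$w0
  w <- fusion_weights(cfg)
  x <- relu(conv2d(fused, w$conv3_w, w$conv3_b, padding = 1L))
  x <- conv2d(x, w$conv4_w, w$conv4_b, padding = 0L)
  minmax_norm(.luminance(minmax_norm(x)))
}

# Shared core so the ablation path can fuse arbitrary view subsets with the
# same machinery (min/max generalize to any n >= 1).
.fuse_values <- function(vals, cfg, mode, rule = "attention") {
  d1 <- dim(vals[[1L]])
  if (mode == "map") {
    if (rule == "average")
      return(minmax_norm(Reduce(`+`, vals) / length(vals)))
    stack <- array(0, c(length(vals), 1L, d1[1L], d1[2L]))
    for (i in seq_along(vals)) stack[i, 1L, , ] <- vals[[i]]
    fused <- attention_rec(stack, cfg)$maps
    return(minmax_norm(fused[1L, , ]))
  }
  .fuse_from_stacks(lapply(vals, .extract_stack, cfg = cfg), cfg, rule)
}

#' Fuse three importance maps into one
#'
#' The full network mode runs extract -> attention-selection -> reconstruct,
#' takes the luminance (channel mean) of the 3-channel reconstruction and
#' min-max normalizes it. The `"map"` mode applies the selection rule directly
#' to the raw maps (`K = 1`), bypassing the convolutions -- a convolution-free
#' reference used for analysis.
#'
#' @param cams list of exactly 3 [importance_map()]s (or matrices) of one shape.
#' @param cfg a [fusion_config()].
#' @param mode `"network"` or `"map"`.
#' @param rule `"attention"` (the selection rule) or `"average"` -- the
#'   plain elementwise-mean fusion of the unmodified framework, kept as the
#'   comparison baseline for the fusion-quality metrics.
#' @param image_id identifier for the fused map.
#' @return an [importance_map()] with `source = "fused"`.
#' @export
fuse_cams <- function(cams, cfg = fusion_config(),
                      mode = c("network", "map"),
                      rule = c("attention", "average"),
                      image_id = NA_character_) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  if (length(cams) != 3L) stop("exactly 3 importance maps are required")
  vals <- lapply(cams, .map_values)
  d1 <- dim(vals[[1L]])
  if (!all(vapply(vals, function(v) identical(dim(v), d1), logical(1L))))
    stop("importance maps must share the same shape")
  tc <- if (inherits(cams[[1L]], "importance_map")) cams[[1L]]$target_class
        else NA_integer_
  importance_map(.fuse_values(vals, cfg, mode, rule), source = "fused",
                 image_id = image_id, target_class = tc)
}

#' Serialize / deserialize a fusion config
#' @param cfg a [fusion_config()].
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `read_fusion_config` returns a `fusion_config`.
#' @export
write_fusion_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$out_channels <- NULL
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fusion_config
#' @export
read_fusion_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  fusion_config(w0 = lst$w0, w1 = lst$w1, eigen = lst$eigen,
                conv_channels = lst$conv_channels, seed = lst$seed)
}
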