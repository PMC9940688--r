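# Desk-scale backbone families with a uniform "activations + gradients at a
# named CAM target layer" contract.  Three families are provided: a residual
# CNN, a ViT-style patch transformer and a Swin-style hierarchical window
# transformer.  The transformer families end in a patch-transformation reshape
# that arranges their token outputs as a square spatial map, which is what
# makes Grad-CAM applicable to them at all.
#
# The classification head in every family reads the CAM target layer through
# global average pooling (optionally followed by a tanh hidden layer), so the
# gradient of a class score with respect to the target-layer activations has a
# closed form; it is validated against finite differences in the test suite.

#' Specify a backbone
#'
#' @param family `"cnn"`, `"vit"` or `"swin"`.
#' @param input_size integer length-2 `(H, W)` in pixels.
#' @param channels base channel width (CNN stage width / image channels for the
#'   transformer token math). Default 8.
#' @param patch_size ViT patch edge P in pixels (ViT only).
#' @param window_down total downsampling factor of the Swin-style hierarchy
#'   (fixed at 32: patch embedding /4 followed by three 2x patch mergings).
#' @param embed_dim transformer embedding width (ViT) or first-stage width
#'   (Swin; the final stage carries `8 * embed_dim` channels).
#' @param depth number of CNN stages or transformer blocks (2--4 is the
#'   intended desk scale).
#' @param num_classes number of output classes.
#' @param head_hidden width of the tanh hidden layer between global average
#'   pooling and the class logits; `0` gives a plain linear head.
#' @param seed integer; the same seed yields bit-identical initial weights.
#' @return a `backbone_spec` object.
#' @export
backbone_spec <- function(family = c("cnn", "vit", "swin"),
                          input_size = c(64L, 64L),
                          channels = 8L,
                          patch_size = 8L,
                          window_down = 32L,
                          embed_dim = 16L,
                          depth = 2L,
                          num_classes = 3L,
                          head_hidden = 16L,
                          seed = 1L) {
  family <- match.arg(family)
  input_size <- as.integer(input_size)
  stopifnot(length(input_size) == 2L, all(input_size >= 8L))
  H <- input_size[1L]; W <- input_size[2L]
  if (family == "vit") {
    P <- as.integer(patch_size)
    if ((H * W) %% (P^2) != 0L || H %% P != 0L || W %% P != 0L)
      stop("invalid vit geometry: H*W must be divisible by patch_size^2 ",
           "(and each side by patch_size); got ", H, "x", W, ", P=", P)
    N <- (H * W) %/% (P^2)
    if (round(sqrt(N))^2 != N)
      stop("invalid vit geometry: patch count N = ", N,
           " is not a perfect square")
  }
  if (family == "swin") {
    wd <- as.integer(window_down)
    if (H %% wd != 0L || W %% wd != 0L)
      stop("invalid swin geometry: input size ", H, "x", W,
           " is not divisible by window_down = ", wd)
  }
  structure(list(family = family, input_size = input_size,
                 channels = as.integer(channels),
                 patch_size = as.integer(patch_size),
                 window_down = as.integer(window_down),
                 embed_dim = as.integer(embed_dim),
                 depth = as.integer(depth),
                 num_classes = as.integer(num_classes),
                 head_hidden = as.integer(head_hidden),
                 seed = as.integer(seed)),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat("<backbone_spec>", x$family, paste(x$input_size, collapse = "x"),
      "depth", x$depth, "classes", x$num_classes, "seed", x$seed, "\n")
  invisible(x)
}

.he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
.lin_init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

.init_block <- function(D) {
  list(ln1_g = rep(1, D), ln1_b = rep(0, D),
       wq = .lin_init(D, D), bq = rep(0, D),
       wk = .lin_init(D, D), bk = rep(0, D),
       wv = .lin_init(D, D), bv = rep(0, D),
       wo = .lin_init(D, D), bo = rep(0, D),
       ln2_g = rep(1, D), ln2_b = rep(0, D),
       mlp1 = .lin_init(D, 2L * D), mb1 = rep(0, 2L * D),
       mlp2 = .lin_init(2L * D, D), mb2 = rep(0, D))
}

.init_head <- function(cstar, spec) {
  if (spec$head_hidden > 0L)
    list(w1 = .lin_init(cstar, spec$head_hidden), b1 = rep(0, spec$head_hidden),
         w2 = .lin_init(spec$head_hidden, spec$num_classes),
         b2 = rep(0, spec$num_classes))
  else
    list(w = .lin_init(cstar, spec$num_classes), b = rep(0, spec$num_classes))
}

#' Build a backbone model from a spec
#'
#' Weights are initialized from `spec$seed` (He-style normals); the returned
#' model exposes a named CAM target layer: the last residual stage output
#' (cnn) or the patch-transformation output (vit, swin).
#'
#' @param spec a [backbone_spec()].
#' @return a `camfuse_backbone` object.
#' @export
build_backbone <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  H <- spec$input_size[1L]; W <- spec$input_size[2L]
  w <- with_seed(spec$seed, {
    if (spec$family == "cnn") {
      ch <- spec$channels
      layers <- list(stem_w = .he_init(c(3, 3, 3, ch), 3 * 9), stem_b = rep(0, ch))
      cin <- ch
      for (s in seq_len(spec$depth)) {
        cs <- ch * 2L^(s - 1L)
        layers[[paste0("down", s, "_w")]] <- .he_init(c(3, 3, cin, cs), cin * 9)
        layers[[paste0("down", s, "_b")]] <- rep(0, cs)
        layers[[paste0("res", s, "a_w")]] <- .he_init(c(3, 3, cs, cs), cs * 9)
        layers[[paste0("res", s, "a_b")]] <- rep(0, cs)
        layers[[paste0("res", s, "b_w")]] <- .he_init(c(3, 3, cs, cs), cs * 9)
        layers[[paste0("res", s, "b_b")]] <- rep(0, cs)
        cin <- cs
      }
      layers$head <- .init_head(cin, spec)
      layers
    } else if (spec$family == "vit") {
      P <- spec$patch_size; D <- spec$embed_dim
      N <- (H * W) %/% (P^2)
      layers <- list(embed_w = .lin_init(P * P * 3L, D), embed_b = rep(0, D),
                     cls = matrix(stats::rnorm(D, 0, 0.02), 1L, D),
                     pos = matrix(stats::rnorm((N + 1L) * D, 0, 0.02), N + 1L, D))
      for (b in seq_len(spec$depth)) layers[[paste0("block", b)]] <- .init_block(D)
      layers$ln_g <- rep(1, D); layers$ln_b <- rep(0, D)
      layers$head <- .init_head(D, spec)
      layers
    } else {
      D <- spec$embed_dim
      G0 <- H %/% 4L
      layers <- list(embed_w = .lin_init(4L * 4L * 3L, D), embed_b = rep(0, D))
      Ds <- D
      for (s in 1:3) {
        layers[[paste0("stage", s)]] <- .init_block(Ds)
        layers[[paste0("merge", s, "_w")]] <- .lin_init(4L * Ds, 2L * Ds)
        layers[[paste0("merge", s, "_b")]] <- rep(0, 2L * Ds)
        Ds <- 2L * Ds
      }
      layers$ln_g <- rep(1, Ds); layers$ln_b <- rep(0, Ds)
      layers$head <- .init_head(Ds, spec)
      layers
    }
  })
  target <- switch(spec$family,
                   cnn = paste0("res", spec$depth, "_out"),
                   vit = "patch_transform",
                   swin = "patch_transform")
  structure(list(spec = spec, weights = w, target_layer = target),
            class = "camfuse_backbone")
}

#' @export
print.camfuse_backbone <- function(x, ...) {
  cat("<camfuse_backbone>", x$spec$family, "target layer:", x$target_layer, "\n")
  invisible(x)
}

# ---- shared transformer pieces ---------------------------------------------

.layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  (xc / sqrt(v + eps)) * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
}

.softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

.n_heads <- function(D) if (D %% 4L == 0L) 4L else if (D %% 2L == 0L) 2L else 1L

# Multi-head self-attention over token rows; `groups` is an optional list of
# index vectors restricting attention to within-group tokens (Swin windows).
.mhsa <- function(x, blk, groups = NULL) {
  D <- ncol(x)
  nh <- .n_heads(D)
  dh <- D %/% nh
  q <- x %*% blk$wq + rep(blk$bq, each = nrow(x))
  k <- x %*% blk$wk + rep(blk$bk, each = nrow(x))
  v <- x %*% blk$wv + rep(blk$bv, each = nrow(x))
  out <- matrix(0, nrow(x), D)
  if (is.null(groups)) groups <- list(seq_len(nrow(x)))
  for (g in groups) {
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      qs <- q[g, cols, drop = FALSE]
      ks <- k[g, cols, drop = FALSE]
      vs <- v[g, cols, drop = FALSE]
      a <- .softmax_rows(tcrossprod(qs, ks) / sqrt(dh))
      out[g, cols] <- a %*% vs
    }
  }
  out %*% blk$wo + rep(blk$bo, each = nrow(x))
}

.transformer_block <- function(x, blk, groups = NULL) {
  x <- x + .mhsa(.layer_norm(x, blk$ln1_g, blk$ln1_b), blk, groups)
  h <- .layer_norm(x, blk$ln2_g, blk$ln2_b)
  h <- .gelu(h %*% blk$mlp1 + rep(blk$mb1, each = nrow(x)))
  x + (h %*% blk$mlp2 + rep(blk$mb2, each = nrow(x)))
}

# Extract non-overlapping p x p patches from an H x W x C image in row-major
# token order (top-left origin, column fastest); each row of the result is one
# flattened patch.
.patchify <- function(img, p) {
  H <- dim(img)[1L]; W <- dim(img)[2L]; C <- dim(img)[3L]
  gh <- H %/% p; gw <- W %/% p
  out <- matrix(0, gh * gw, p * p * C)
  for (r in seq_len(gh)) for (c in seq_len(gw)) {
    t <- (r - 1L) * gw + c
    out[t, ] <- as.vector(img[((r - 1L) * p + 1L):(r * p),
                              ((c - 1L) * p + 1L):(c * p), ])
  }
  out
}

# ---- patch transformation --------------------------------------------------

# Linear index map between a (N, C) row-major token matrix and a (C, s, s)
# channel-first spatial array; a pure permutation, hence exactly invertible.
.pt_lin <- function(C, s) {
  N <- s * s
  row_of_t <- (seq_len(N) - 1L) %/% s
  col_of_t <- (seq_len(N) - 1L) %% s
  outer(seq_len(C), row_of_t * C + col_of_t * C * s, `+`)
}

#' Patch transformation for ViT-style token outputs
#'
#' Drops the leading class token and arranges the remaining `K - 1` tokens as
#' a square channel-first spatial map (row-major, top-left origin), so that
#' Grad-CAM can treat the transformer output like a convolutional feature map.
#'
#' @param tokens `(K, C)` matrix whose first row is the class token.
#' @return `(C, sqrt(K-1), sqrt(K-1))` array.
#' @seealso [patch_untransform_vit()] for the exact inverse.
#' @export
patch_transform_vit <- function(tokens) {
  stopifnot(is.matrix(tokens))
  if (nrow(tokens) < 2L) stop("need at least 2 tokens (class token + 1 patch)")
  N <- nrow(tokens) - 1L
  s <- as.integer(round(sqrt(N)))
  if (s * s != N)
    stop("token count minus the class token (", N, ") is not a perfect square")
  C <- ncol(tokens)
  arr <- numeric(C * N)
  arr[as.vector(.pt_lin(C, s))] <- as.vector(t(tokens[-1L, , drop = FALSE]))
  dim(arr) <- c(C, s, s)
  arr
}

#' Inverse of [patch_transform_vit()] (recovers the patch tokens, bit-exact)
#' @param x `(C, s, s)` array.
#' @return `(s^2, C)` token matrix (class token excluded).
#' @export
patch_untransform_vit <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L, d[2L] == d[3L])
  t(matrix(x[as.vector(.pt_lin(d[1L], d[2L]))], d[1L], d[2L] * d[3L]))
}

#' Patch transformation for Swin-style token outputs
#'
#' Row-major reshape of a `(G^2, C)` token matrix into a `(C, G, G)`
#' channel-first spatial map, where `G = H / window_down`.
#'
#' @param tokens `(G^2, C)` token matrix.
#' @param grid the grid side G the token count must match.
#' @return `(C, G, G)` array.
#' @export
patch_transform_swin <- function(tokens, grid) {
  stopifnot(is.matrix(tokens))
  grid <- as.integer(grid)
  if (nrow(tokens) != grid * grid)
    stop("token count ", nrow(tokens), " does not match the declared ",
         grid, "x", grid, " grid")
  C <- ncol(tokens)
  arr <- numeric(C * grid * grid)
  arr[as.vector(.pt_lin(C, grid))] <- as.vector(t(tokens))
  dim(arr) <- c(C, grid, grid)
  arr
}

#' Inverse of [patch_transform_swin()] (bit-exact)
#' @param x `(C, G, G)` array.
#' @return `(G^2, C)` token matrix.
#' @export
patch_untransform_swin <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L, d[2L] == d[3L])
  t(matrix(x[as.vector(.pt_lin(d[1L], d[2L]))], d[1L], d[2L] * d[3L]))
}

# ---- forward passes to the CAM target layer --------------------------------

.forward_cnn <- function(model, img) {
  w <- model$weights
  x <- relu(conv2d(img, w$stem_w, w$stem_b))
  for (s in seq_len(model$spec$depth)) {
    x <- relu(conv2d(x, w[[paste0("down", s, "_w")]], w[[paste0("down", s, "_b")]],
                     stride = 2L, padding = 1L))
    r <- relu(conv2d(x, w[[paste0("res", s, "a_w")]], w[[paste0("res", s, "a_b")]]))
    r <- conv2d(r, w[[paste0("res", s, "b_w")]], w[[paste0("res", s, "b_b")]])
    x <- relu(x + r)
  }
  aperm(x, c(3L, 1L, 2L))
}

.forward_vit <- function(model, img) {
  sp <- model$spec; w <- model$weights
  tok <- .patchify(img, sp$patch_size) %*% w$embed_w +
    rep(w$embed_b, each = (sp$input_size[1L] * sp$input_size[2L]) %/% sp$patch_size^2)
  x <- rbind(w$cls, tok) + w$pos
  for (b in seq_len(sp$depth)) x <- .transformer_block(x, w[[paste0("block", b)]])
  x <- .layer_norm(x, w$ln_g, w$ln_b)
  patch_transform_vit(x)
}

.swin_windows <- function(G, w, shift) {
  # token index groups (row-major grid) for w x w windows after a cyclic
  # shift of the grid by `shift` in both directions
  idx <- matrix(seq_len(G * G), G, G, byrow = TRUE)  # idx[r, c] = token id
  if (shift > 0L) {
    ord <- function(n, s) ((seq_len(n) - 1L + s) %% n) + 1L
    idx <- idx[ord(G, shift), ord(G, shift)]
  }
  nw <- G %/% w
  groups <- vector("list", nw * nw)
  g <- 1L
  for (wr in seq_len(nw)) for (wc in seq_len(nw)) {
    groups[[g]] <- as.vector(idx[((wr - 1L) * w + 1L):(wr * w),
                                 ((wc - 1L) * w + 1L):(wc * w)])
    g <- g + 1L
  }
  groups
}

.swin_merge <- function(x, G, wmat, b) {
  # 2x2 neighborhood concat (row-major grid) followed by a linear projection
  Gn <- G %/% 2L
  Dn <- ncol(x)
  out <- matrix(0, Gn * Gn, 4L * Dn)
  for (r in seq_len(Gn)) for (c in seq_len(Gn)) {
    t00 <- (2L * r - 2L) * G + (2L * c - 1L)
    t01 <- t00 + 1L
    t10 <- t00 + G
    t11 <- t10 + 1L
    out[(r - 1L) * Gn + c, ] <- c(x[t00, ], x[t01, ], x[t10, ], x[t11, ])
  }
  out %*% wmat + rep(b, each = Gn * Gn)
}

.forward_swin <- function(model, img) {
  sp <- model$spec; w <- model$weights
  G <- sp$input_size[1L] %/% 4L
  x <- .patchify(img, 4L) %*% w$embed_w + rep(w$embed_b, each = G * G)
  for (s in 1:3) {
    # largest window size <= 4 that tiles the current grid exactly
    win <- max(which(G %% 1:4 == 0 & 1:4 <= G))
    shift <- if (s == 2L && win > 1L) win %/% 2L else 0L
    x <- .transformer_block(x, w[[paste0("stage", s)]], .swin_windows(G, win, shift))
    x <- .swin_merge(x, G, w[[paste0("merge", s, "_w")]], w[[paste0("merge", s, "_b")]])
    G <- G %/% 2L
  }
  x <- .layer_norm(x, w$ln_g, w$ln_b)
  patch_transform_swin(x, G)
}

# Activations at the CAM target layer, channel-first (C*, u, v).
backbone_features <- function(model, image) {
  stopifnot(inherits(model, "camfuse_backbone"))
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L ||
      d[1L] != model$spec$input_size[1L] || d[2L] != model$spec$input_size[2L])
    stop("image must be ", model$spec$input_size[1L], "x",
         model$spec$input_size[2L], "x3; got ", paste(d, collapse = "x"))
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image values must lie in [0, 1]")
  switch(model$spec$family,
         cnn = .forward_cnn(model, image),
         vit = .forward_vit(model, image),
         swin = .forward_swin(model, image))
}

# Classification head: global average pooling over the spatial axes of the
# target-layer activations, then either a linear map or a tanh hidden layer.
head_forward <- function(model, acts) {
  g <- apply(acts, 1L, mean)
  hd <- model$weights$head
  if (!is.null(hd$w1)) {
    h1 <- tanh(as.vector(crossprod(hd$w1, g)) + hd$b1)
    as.vector(crossprod(hd$w2, h1)) + hd$b2
  } else {
    as.vector(crossprod(hd$w, g)) + hd$b
  }
}

# Closed-form d score[t] / d activations: backprop through the head only.
head_grad <- function(model, acts, t) {
  g <- apply(acts, 1L, mean)
  hd <- model$weights$head
  dg <- if (!is.null(hd$w1)) {
    h1 <- tanh(as.vector(crossprod(hd$w1, g)) + hd$b1)
    as.vector(hd$w1 %*% (hd$w2[, t] * (1 - h1^2)))
  } else {
    hd$w[, t]
  }
  uv <- dim(acts)[2L] * dim(acts)[3L]
  array(rep(dg / uv, times = uv), dim(acts))
}

#' Forward pass with gradients at the CAM target layer
#'
#' Runs the backbone on one image and returns the target-layer activations
#' together with the gradient of one class's pre-softmax logit with respect to
#' those activations -- the two ingredients Grad-CAM needs.
#'
#' @param model a [build_backbone()] model.
#' @param image `H x W x 3` array in `[0, 1]` matching the spec input size.
#' @param target_class 1-based class index, or `"argmax"` for the top-scoring
#'   class.
#' @return a `backbone_output` with fields `activations` and `gradients`
#'   (both `(C*, u, v)`), `class_scores` (pre-softmax logits) and
#'   `target_class`.
#' @export
forward_with_grads <- function(model, image, target_class = "argmax") {
  acts <- backbone_features(model, image)
  scores <- head_forward(model, acts)
  t <- if (identical(target_class, "argmax")) which.max(scores)
       else as.integer(target_class)
  if (t < 1L || t > length(scores))
    stop("target_class ", t, " out of range 1..", length(scores))
  structure(list(activations = acts,
                 gradients = head_grad(model, acts, t),
                 class_scores = scores,
                 target_class = t),
            class = "backbone_output")
}

#' @export
print.backbone_output <- function(x, ...) {
  d <- dim(x$activations)
  cat("<backbone_output> activations", paste(d, collapse = "x"),
      " target class", x$target_class, "\n")
  invisible(x)
}

#' Save / load backbone weights
#'
#' Weights are stored as a single-file archive (a named list keyed by layer
#' name). Loading validates that the layer names and shapes match the model.
#'
#' @param model a `camfuse_backbone`.
#' @param path file path.
#' @return `load_backbone_weights` returns the model with weights replaced.
#' @export
save_backbone_weights <- function(model, path) {
  stopifnot(inherits(model, "camfuse_backbone"))
  saveRDS(model$weights, path)
  invisible(path)
}

#' @rdname save_backbone_weights
#' @export
load_backbone_weights <- function(model, path) {
  w <- readRDS(path)
  if (!setequal(names(w), names(model$weights)))
    stop("weights file does not match the model's layer names")
  for (nm in names(model$weights)) {
    if (!identical(dim(model$weights[[nm]]), dim(w[[nm]])) ||
        length(model$weights[[nm]]) != length(w[[nm]]))
      stop("shape mismatch for layer ", nm)
  }
  model$weights <- w[names(model$weights)]
  model
}

#' Serialize / deserialize a backbone spec
#'
#' @param spec a [backbone_spec()].
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `read_backbone_spec` returns a `backbone_spec`.
#' @export
write_backbone_spec <- function(spec, path) {
  stopifnot(inherits(spec, "backbone_spec"))
  lst <- unclass(spec)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_backbone_spec
#' @export
read_backbone_spec <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(backbone_spec, lst)
}
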