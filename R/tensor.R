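# Low-level numeric kernels shared by the backbones, the fusion network and the
# augmentation engine.  Images are H x W x C arrays in [0, 1] (the png package
# convention); feature tensors are kept channel-last (H, W, C) internally and
# transposed to the channel-first (C, u, v) layout only at module boundaries.

.camfuse_cache <- new.env(parent = emptyenv())

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic entry points funnel through
# this so that a seed argument never leaks RNG state into the session.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

.gelu <- function(x) x * stats::pnorm(x)

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Min-max rescale to [0, 1].  A constant map carries no contrast to rescale:
# all-zero input stays zero (fully suppressed evidence); a positive constant
# becomes one (uniformly important).
minmax_norm <- function(x, eps = 1e-12) {
  lo <- min(x)
  hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi)) stop("minmax_norm: non-finite values")
  if (hi - lo < eps) {
    out <- x
    out[] <- if (hi > eps) 1 else 0
    return(out)
  }
  (x - lo) / (hi - lo)
}

# Pad the first two dims of a matrix or H x W x C array.
.pad_hw <- function(x, p, mode = c("zero", "reflect")) {
  if (p == 0L) return(x)
  mode <- match.arg(mode)
  d <- dim(x)
  was_mat <- length(d) == 2L
  if (was_mat) dim(x) <- c(d, 1L)
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  out <- array(0, c(H + 2L * p, W + 2L * p, C))
  out[(p + 1L):(p + H), (p + 1L):(p + W), ] <- x
  if (mode == "reflect") {
    ri <- .reflect_index(seq_len(H + 2L * p) - 1L - p, H) + 1L
    rj <- .reflect_index(seq_len(W + 2L * p) - 1L - p, W) + 1L
    out <- x[ri, rj, , drop = FALSE]
  }
  if (was_mat) dim(out) <- dim(out)[1:2]
  out
}

# Symmetric ("mirror with edge repeat") fold of 0-based indices into [0, n-1].
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * n
  m <- ((i %% p) + p) %% p
  ifelse(m > n - 1L, p - 1L - m, m)
}

# Cached im2col index matrix: rows are output positions (column-major over the
# H' x W' grid), columns are kernel taps (dy fastest, then dx, then channel) --
# matching the column-major flattening of a (kh, kw, Cin, Cout) weight array.
.im2col_idx <- function(Hp, Wp, C, kh, kw, stride, Ho, Wo) {
  key <- paste(Hp, Wp, C, kh, kw, stride, Ho, Wo, sep = "_")
  hit <- .camfuse_cache[[key]]
  if (!is.null(hit)) return(hit)
  i0 <- seq.int(1L, by = stride, length.out = Ho)
  j0 <- seq.int(1L, by = stride, length.out = Wo)
  base <- rep(i0, times = Wo) + (rep(j0, each = Ho) - 1L) * Hp
  offs <- as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, `+`))
  offs <- as.vector(outer(offs, (0:(C - 1L)) * Hp * Wp, `+`))
  idx <- matrix(base, length(base), length(offs)) +
    matrix(offs, length(base), length(offs), byrow = TRUE)
  storage.mode(idx) <- "integer"
  .camfuse_cache[[key]] <- idx
  idx
}

#' 2-D convolution (cross-correlation) for channel-last arrays
#'
#' im2col + BLAS matrix multiply.  `w` has dim (kh, kw, Cin, Cout); odd kernel
#' sizes with `padding = (k - 1) / 2` preserve the spatial size at stride 1.
#'
#' @param x H x W x Cin array (a matrix is treated as single-channel).
#' @param w kernel array (kh, kw, Cin, Cout).
#' @param bias length-Cout numeric or NULL.
#' @param stride positive integer stride.
#' @param padding integer pad width on every side; default "same" for odd kernels.
#' @param pad_mode "zero" or "reflect".
#' @return H' x W' x Cout array.
#' @keywords internal
conv2d <- function(x, w, bias = NULL, stride = 1L,
                   padding = NULL, pad_mode = "zero") {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  dw <- dim(w)
  stopifnot(length(dw) == 4L, dim(x)[3L] == dw[3L])
  kh <- dw[1L]; kw <- dw[2L]; Cin <- dw[3L]; Cout <- dw[4L]
  if (is.null(padding)) padding <- (kh - 1L) %/% 2L
  xp <- .pad_hw(x, padding, pad_mode)
  Hp <- dim(xp)[1L]; Wp <- dim(xp)[2L]
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  idx <- .im2col_idx(Hp, Wp, Cin, kh, kw, as.integer(stride), Ho, Wo)
  cols <- xp[idx]
  dim(cols) <- dim(idx)
  dim(w) <- c(kh * kw * Cin, Cout)
  out <- cols %*% w
  if (!is.null(bias) && any(bias != 0))
    out <- out + rep(bias, each = nrow(out))
  dim(out) <- c(Ho, Wo, Cout)
  out
}

# Bilinear sample of a matrix at fractional 0-based coordinates (vectors xs =
# column coord, ys = row coord), coordinates already folded into range.
.bilinear_gather <- function(m, ys, xs) {
  H <- nrow(m); W <- ncol(m)
  ys <- pmin(pmax(ys, 0), H - 1)
  xs <- pmin(pmax(xs, 0), W - 1)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- ys - y0; fx <- xs - x0
  v00 <- m[(x0) * H + y0 + 1]
  v01 <- m[(x1) * H + y0 + 1]
  v10 <- m[(x0) * H + y1 + 1]
  v11 <- m[(x1) * H + y1 + 1]
  v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
}

#' Bilinear resize of a matrix or H x W x C array
#'
#' Output pixel centers map to input coordinates as
#' `src = (dst + 0.5) * size_in / size_out - 0.5` (align_corners = FALSE), with
#' edge clamping -- the convention under which importance maps from backbones of
#' different native resolutions stay spatially comparable after upsampling.
#'
#' @param x matrix or 3-d array.
#' @param out_h,out_w output size in pixels.
#' @return resized matrix or array.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  stopifnot(out_h >= 1, out_w >= 1)
  d <- dim(x)
  was_mat <- length(d) == 2L
  if (was_mat) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (d[1L] == out_h && d[2L] == out_w) {
    if (was_mat) dim(x) <- d[1:2]
    return(x)
  }
  ys <- ((seq_len(out_h) - 0.5) * d[1L] / out_h) - 0.5
  xs <- ((seq_len(out_w) - 0.5) * d[2L] / out_w) - 0.5
  yy <- rep(ys, times = out_w)
  xx <- rep(xs, each = out_h)
  out <- array(0, c(out_h, out_w, d[3L]))
  for (c in seq_len(d[3L]))
    out[, , c] <- matrix(.bilinear_gather(matrix(x[, , c], d[1L], d[2L]),
                                          yy, xx), out_h, out_w)
  if (was_mat) dim(out) <- c(out_h, out_w)
  out
}

# One affine resampling pass with reflection padding: output pixel (0-based,
# centered at the image center) maps back to
#   src = R(-angle) %*% (dst / zoom) + center - shift_px.
# Used by the augmentation engine, one transform per call.
warp_affine <- function(img, angle = 0, zoom = 1, shift_frac = c(0, 0)) {
  d <- dim(img)
  was_mat <- length(d) == 2L
  if (was_mat) dim(img) <- c(d, 1L)
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  rr <- rep(seq_len(H) - 1, times = W) - cy
  cc <- rep(seq_len(W) - 1, each = H) - cx
  th <- -angle * pi / 180
  xs <- (cos(th) * cc - sin(th) * rr) / zoom + cx - shift_frac[2L] * W
  ys <- (sin(th) * cc + cos(th) * rr) / zoom + cy - shift_frac[1L] * H
  # reflect fractional coords into range by reflecting the integer lattice
  out <- array(0, d)
  for (ch in seq_len(d[3L])) {
    m <- img[, , ch]
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    ry0 <- .reflect_index(y0, H); ry1 <- .reflect_index(y0 + 1, H)
    rx0 <- .reflect_index(x0, W); rx1 <- .reflect_index(x0 + 1, W)
    v00 <- m[rx0 * H + ry0 + 1]
    v01 <- m[rx1 * H + ry0 + 1]
    v10 <- m[rx0 * H + ry1 + 1]
    v11 <- m[rx1 * H + ry1 + 1]
    out[, , ch] <- matrix(v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
                            v10 * fy * (1 - fx) + v11 * fy * fx, H, W)
  }
  if (was_mat) dim(out) <- d[1:2]
  out
}

# Separable Gaussian blur with reflection padding.  Sigma follows the common
# kernel-size heuristic sigma = 0.3 * ((k - 1) / 2 - 1) + 0.8.
gaussian_blur <- function(img, ksize) {
  ksize <- as.integer(ksize)
  stopifnot(ksize >= 1L, ksize %% 2L == 1L)
  if (ksize == 1L) return(img)
  sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  half <- (ksize - 1L) %/% 2L
  k1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- array(outer(k1, k1), c(ksize, ksize, 1L, 1L))
  d <- dim(img)
  was_mat <- length(d) == 2L
  if (was_mat) dim(img) <- c(d, 1L)
  out <- img
  for (ch in seq_len(dim(img)[3L])) {
    m <- array(img[, , ch], c(dim(img)[1:2], 1L))
    out[, , ch] <- conv2d(m, k2, padding = half, pad_mode = "reflect")[, , 1L]
  }
  if (was_mat) dim(out) <- d[1:2]
  out
}

# Mean over the channel axis of an H x W x C array.
.luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  rowMeans(arr, dims = 2L)
}
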