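# Shared fixtures: tiny models, random maps and hand-built backbone outputs.

rand_map <- function(h, w, seed) {
  withr::with_seed(seed, matrix(stats::runif(h * w), h, w))
}

rand_image <- function(h, w, seed) {
  withr::with_seed(seed, array(stats::runif(h * w * 3), c(h, w, 3L)))
}

# A backbone output built directly from activation/gradient arrays.
fake_output <- function(acts, grads, scores = c(1, 0), target = 1L) {
  structure(list(activations = acts, gradients = grads,
                 class_scores = scores, target_class = target),
            class = "backbone_output")
}

# 1-class CNN whose score is exactly the mean of its single activation map:
# channels = 1, depth = 1, linear head with unit weight.
mean_score_model <- function(input = c(16L, 16L)) {
  sp <- backbone_spec("cnn", input_size = input, channels = 1L, depth = 1L,
                      num_classes = 1L, head_hidden = 0L, seed = 99L)
  m <- build_backbone(sp)
  m$weights$head$w <- matrix(1, 1L, 1L)
  m$weights$head$b <- 0
  m
}

# Brute-force Grad-CAM at native resolution: explicit loops, no vectorized
# shortcuts; mirrors the definition, not the implementation.
brute_cam <- function(out) {
  d <- dim(out$activations)
  w <- numeric(d[1L])
  for (k in seq_len(d[1L])) {
    s <- 0
    for (u in seq_len(d[2L])) for (v in seq_len(d[3L]))
      s <- s + out$gradients[k, u, v]
    w[k] <- s / (d[2L] * d[3L])
  }
  raw <- matrix(0, d[2L], d[3L])
  for (u in seq_len(d[2L])) for (v in seq_len(d[3L])) {
    acc <- 0
    for (k in seq_len(d[1L])) acc <- acc + w[k] * out$activations[k, u, v]
    raw[u, v] <- max(acc, 0)
  }
  raw
}

# Finite-difference gradient of score[target] w.r.t. each target-layer
# activation cell, through the classification head.
fd_head_grad <- function(model, acts, target, eps = 1e-5) {
  g <- array(0, dim(acts))
  for (i in seq_along(acts)) {
    ap <- acts; ap[i] <- ap[i] + eps
    am <- acts; am[i] <- am[i] - eps
    g[i] <- (camfuse:::head_forward(model, ap)[target] -
               camfuse:::head_forward(model, am)[target]) / (2 * eps)
  }
  g
}

tiny_synth_spec <- function(per_class = 4L, seed = 1L) {
  synthetic_spec(n_classes = 3L, per_class = per_class, image_side = 64L,
                 seed = seed)
}
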