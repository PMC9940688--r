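test_that("patch transformation reshapes tokens to square maps and back, bit-exact", {
  # ViT-style: class token dropped, K - 1 tokens arranged row-major
  tok <- matrix(rnorm(5 * 8), 5, 8)
  x <- patch_transform_vit(tok)
  expect_identical(dim(x), c(8L, 2L, 2L))
  expect_identical(patch_untransform_vit(x), tok[-1L, ])
  # token t sits at (row, col) row-major with channels first
  expect_identical(x[, 1L, 2L], tok[3L, ])

  big <- matrix(rnorm(197 * 12), 197, 12)
  xb <- patch_transform_vit(big)
  expect_identical(dim(xb), c(12L, 14L, 14L))
  expect_identical(patch_untransform_vit(xb), big[-1L, ])

  # Swin-style: plain row-major reshape, lossless
  tk <- matrix(rnorm(49 * 96), 49, 96)
  xs <- patch_transform_swin(tk, 7L)
  expect_identical(dim(xs), c(96L, 7L, 7L))
  expect_identical(patch_untransform_swin(xs), tk)
  xs2 <- patch_transform_swin(matrix(rnorm(4 * 8), 4, 8), 2L)
  expect_identical(dim(xs2), c(8L, 2L, 2L))

  expect_error(patch_transform_vit(matrix(rnorm(11 * 4), 11, 4)),
               "perfect square")
  expect_error(patch_transform_vit(matrix(rnorm(4), 1, 4)), "at least 2")
  expect_error(patch_transform_swin(matrix(rnorm(50 * 3), 50, 3), 7L),
               "does not match")
})

test_that("CAM target-layer shapes follow the analytic formulas per family", {
  cases <- list(
    list(fam = "cnn", size = c(64L, 64L), depth = 2L, args = list(channels = 4L),
         want = c(8L, 16L, 16L)),      # width doubles per stage, stride 2 each
    list(fam = "cnn", size = c(32L, 32L), depth = 3L, args = list(channels = 2L),
         want = c(8L, 4L, 4L)),
    list(fam = "vit", size = c(32L, 32L), depth = 1L,
         args = list(patch_size = 8L, embed_dim = 8L), want = c(8L, 4L, 4L)),
    list(fam = "vit", size = c(48L, 48L), depth = 1L,
         args = list(patch_size = 8L, embed_dim = 4L), want = c(4L, 6L, 6L)),
    list(fam = "swin", size = c(64L, 64L), depth = 1L,
         args = list(embed_dim = 4L), want = c(32L, 2L, 2L)),
    list(fam = "swin", size = c(96L, 96L), depth = 1L,
         args = list(embed_dim = 2L), want = c(16L, 3L, 3L))
  )
  for (cs in cases) {
    sp <- do.call(backbone_spec, c(list(family = cs$fam, input_size = cs$size,
                                        depth = cs$depth, num_classes = 2L,
                                        seed = 3L), cs$args))
    m <- build_backbone(sp)
    out <- forward_with_grads(m, rand_image(cs$size[1], cs$size[2], 11L))
    expect_identical(dim(out$activations), cs$want,
                     label = paste(cs$fam, paste(cs$size, collapse = "x")))
    expect_identical(dim(out$gradients), dim(out$activations))
  }
})

test_that("invalid geometries are rejected with the violated constraint named", {
  expect_error(backbone_spec("vit", input_size = c(60L, 60L), patch_size = 8L),
               "divisible by patch_size")
  expect_error(backbone_spec("vit", input_size = c(32L, 64L), patch_size = 8L),
               "not a perfect square")
  expect_error(backbone_spec("swin", input_size = c(48L, 48L)),
               "not divisible by window_down")
})

test_that("weight initialization is seed-deterministic", {
  sp <- backbone_spec("vit", input_size = c(32L, 32L), patch_size = 8L,
                      embed_dim = 8L, depth = 2L, seed = 7L)
  m1 <- build_backbone(sp)
  m2 <- build_backbone(sp)
  expect_identical(m1$weights, m2$weights)
  sp$seed <- 8L
  expect_false(identical(build_backbone(sp)$weights, m1$weights))
})

test_that("gradients at the target layer match the analytic toy and argmax resolution", {
  m <- mean_score_model(c(16L, 16L))
  img <- rand_image(16L, 16L, 5L)
  out <- forward_with_grads(m, img, target_class = 1L)
  uv <- prod(dim(out$activations)[2:3])
  # score is the mean of the single activation map -> gradient 1/(u*v) everywhere
  expect_equal(as.vector(out$gradients), rep(1 / uv, uv), tolerance = 1e-12)
  expect_equal(out$class_scores[1], mean(out$activations), tolerance = 1e-12)

  sp <- backbone_spec("cnn", input_size = c(16L, 16L), channels = 2L,
                      depth = 2L, num_classes = 3L, head_hidden = 8L, seed = 4L)
  m3 <- build_backbone(sp)
  oa <- forward_with_grads(m3, img, "argmax")
  ox <- forward_with_grads(m3, img, which.max(oa$class_scores))
  expect_identical(oa$gradients, ox$gradients)
  expect_error(forward_with_grads(m3, img, 9L), "out of range")
  expect_error(forward_with_grads(m3, rand_image(8L, 8L, 1L)), "must be")
})

test_that("autodiff head gradients agree with central finite differences", {
  fams <- list(
    list(family = "cnn", input_size = c(16L, 16L), channels = 2L, depth = 2L),
    list(family = "vit", input_size = c(16L, 16L), patch_size = 4L,
         embed_dim = 8L, depth = 1L),
    list(family = "swin", input_size = c(32L, 32L), embed_dim = 2L, depth = 1L)
  )
  for (fa in fams) for (seed in 1:4) {
    sp <- do.call(backbone_spec,
                  c(fa, list(num_classes = 3L, head_hidden = 8L, seed = seed)))
    m <- build_backbone(sp)
    img <- rand_image(sp$input_size[1], sp$input_size[2], 100L + seed)
    out <- forward_with_grads(m, img, 2L)
    fd <- fd_head_grad(m, out$activations, 2L)
    sel <- abs(out$gradients) > 1e-6
    expect_true(any(sel))
    rel <- abs(out$gradients[sel] - fd[sel]) / abs(out$gradients[sel])
    expect_lt(max(rel), 1e-3)
  }
})

test_that("weights round-trip through the single-file archive", {
  sp <- backbone_spec("cnn", input_size = c(16L, 16L), channels = 2L,
                      depth = 1L, num_classes = 2L, seed = 1L)
  m <- build_backbone(sp)
  f <- withr::local_tempfile(fileext = ".rds")
  save_backbone_weights(m, f)
  m2 <- build_backbone(backbone_spec("cnn", input_size = c(16L, 16L),
                                     channels = 2L, depth = 1L,
                                     num_classes = 2L, seed = 2L))
  m2 <- load_backbone_weights(m2, f)
  expect_identical(m2$weights, m$weights)
  bad <- build_backbone(backbone_spec("cnn", input_size = c(16L, 16L),
                                      channels = 4L, depth = 1L,
                                      num_classes = 2L, seed = 2L))
  expect_error(load_backbone_weights(bad, f), "mismatch")
})

test_that("backbone specs serialize to YAML and JSON", {
  sp <- backbone_spec("vit", input_size = c(32L, 32L), patch_size = 8L,
                      embed_dim = 8L, depth = 2L, num_classes = 5L, seed = 3L)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_backbone_spec(sp, f)
    expect_equal(read_backbone_spec(f), sp)
  }
})
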