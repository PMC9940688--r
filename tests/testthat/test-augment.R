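test_that("plans include each method with its probability and draw within limits", {
  specs <- augmentation_specs()
  p0 <- specs; p0$probability[] <- 0
  expect_length(sample_plan(p0, 1L), 0)
  p1 <- specs; p1$probability[] <- 1
  full <- sample_plan(p1, 1L)
  expect_identical(vapply(full, `[[`, "", "method"), specs$method)

  # every drawn parameter lies inside its interval; blur kernels odd
  for (seed in 1:300) {
    for (s in sample_plan(specs, seed)) {
      lim <- specs$limits[[match(s$method, specs$method)]]
      switch(s$method,
        BC = {
          expect_gte(s$params$brightness, lim$brightness[1])
          expect_lte(s$params$brightness, lim$brightness[2])
          expect_gte(s$params$contrast, lim$contrast[1])
          expect_lte(s$params$contrast, lim$contrast[2])
        },
        Shift = {
          expect_true(all(c(s$params$dy, s$params$dx) >= lim$shift[1]))
          expect_true(all(c(s$params$dy, s$params$dx) <= lim$shift[2]))
        },
        Scale = expect_true(s$params$scale >= lim$scale[1] &&
                              s$params$scale <= lim$scale[2]),
        Rotate = expect_true(s$params$angle >= lim$angle[1] &&
                               s$params$angle <= lim$angle[2]),
        GB = {
          expect_true(s$params$kernel %in% c(3, 5, 7))
        },
        Sharpen = {
          expect_gte(s$params$alpha, lim$alpha[1])
          expect_lte(s$params$alpha, lim$alpha[2])
          expect_gte(s$params$lightness, lim$lightness[1])
          expect_lte(s$params$lightness, lim$lightness[2])
        },
        HF = expect_length(s$params, 0))
    }
  }
  expect_identical(plan_to_json(sample_plan(specs, 42L)),
                   plan_to_json(sample_plan(specs, 42L)))
})

test_that("applying transforms preserves shape, range and known identities", {
  img <- rand_image(32L, 32L, 7L)
  expect_identical(apply_plan(img, structure(list(), class = "augmentation_plan")),
                   img)
  hf <- list(method = "HF", params = list())
  plan2 <- structure(list(hf, hf), class = "augmentation_plan")
  expect_identical(apply_plan(img, plan2), img)  # flip is an involution

  # brightness/contrast follows its affine form exactly
  bc <- structure(list(list(method = "BC",
                            params = list(brightness = 0.1, contrast = -0.2))),
                  class = "augmentation_plan")
  expect_equal(apply_plan(img, bc),
               clip01((img - 0.5) * 0.8 + 0.6), tolerance = 1e-12)

  specs <- augmentation_specs()
  for (seed in c(2L, 3L, 4L)) {
    out <- apply_plan(img, sample_plan(specs, seed))
    expect_identical(dim(out), dim(img))
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
})

test_that("rotation round-trips within interpolation tolerance on the interior", {
  img <- gaussian_blur(rand_image(48L, 48L, 15L), 5L)  # band-limit first
  for (theta in c(17, -31)) {
    fwd <- structure(list(list(method = "Rotate", params = list(angle = theta))),
                     class = "augmentation_plan")
    bwd <- structure(list(list(method = "Rotate", params = list(angle = -theta))),
                     class = "augmentation_plan")
    rt <- apply_plan(apply_plan(img, fwd), bwd)
    core <- 13:36
    mse <- mean((rt[core, core, ] - img[core, core, ])^2)
    psnr <- 10 * log10(1 / mse)
    expect_gt(psnr, 30)
  }
})

test_that("balance_dataset tops classes up deterministically with recorded plans", {
  dir <- withr::local_tempdir()
  man <- list()
  for (k in 1:2) for (i in seq_len(c(3L, 6L)[k])) {
    p <- file.path(dir, sprintf("c%d_%d.png", k, i))
    png::writePNG(rand_image(16L, 16L, k * 100L + i), p)
    man[[length(man) + 1L]] <- tibble::tibble(path = p,
                                              label = paste0("c", k))
  }
  man <- dplyr::bind_rows(man)
  out <- balance_dataset(man, target_per_class = 6L, rng_seed = 11L,
                         dir = file.path(dir, "aug"))
  expect_equal(sum(out$label == "c1"), 6L)
  expect_equal(sum(out$label == "c2"), 6L)  # already at target: untouched
  expect_equal(sum(out$origin == "augmented"), 3L)
  expect_true(all(out$path[out$origin == "original"] %in% man$path))
  aug <- out[out$origin == "augmented", ]
  expect_true(all(!is.na(aug$plan)))
  plans <- lapply(aug$plan, plan_from_json)
  expect_true(all(vapply(plans, inherits, TRUE, "augmentation_plan")))
  out2 <- balance_dataset(man, target_per_class = 6L, rng_seed = 11L,
                          dir = file.path(dir, "aug2"))
  expect_identical(out$plan, out2$plan)
  expect_identical(basename(out$path), basename(out2$path))
  expect_error(balance_dataset(man[0, ], 5L), "at least one")
})
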