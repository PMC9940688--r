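test_that("SF and AG have their closed-form values on canonical images", {
  cst <- matrix(0.37, 8, 8)
  expect_equal(spatial_frequency(cst, 1), 0)
  expect_equal(average_gradient(cst, 1), 0)

  chk <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(spatial_frequency(chk, 1), 1)
  expect_equal(average_gradient(chk, 1), 1)

  N <- 16L
  ramp <- matrix(rep((0:(N - 1)) / (N - 1), each = N), N, N)
  expect_equal(average_gradient(ramp, 1), sqrt(0.5) / (N - 1), tolerance = 1e-12)

  # homogeneity of degree 1 in the intensity scale
  m <- rand_map(6L, 7L, 12L)
  expect_equal(spatial_frequency(m, 2), 2 * spatial_frequency(m, 1))
  expect_equal(average_gradient(m, 510), 2 * average_gradient(m, 255))
  # translation invariance
  expect_equal(spatial_frequency(m + 0.3, 1), spatial_frequency(m, 1))
  expect_equal(average_gradient(m + 0.3, 1), average_gradient(m, 1))

  expect_error(spatial_frequency(matrix(1, 1, 1)), "at least 2")
  expect_error(average_gradient(matrix(1, 2, 1)), "at least 2")
})

test_that("SF and AG agree with brute-force double loops on random images", {
  for (seed in 1:40) {
    m <- rand_map(5L + seed %% 4L, 6L + seed %% 3L, seed)
    M <- nrow(m); N <- ncol(m)
    rf2 <- cf2 <- 0
    for (i in 1:M) for (j in 2:N) rf2 <- rf2 + (m[i, j] - m[i, j - 1])^2
    for (i in 2:M) for (j in 1:N) cf2 <- cf2 + (m[i, j] - m[i - 1, j])^2
    sf <- sqrt(rf2 / (M * N) + cf2 / (M * N))
    ag <- 0
    for (i in 1:(M - 1)) for (j in 1:(N - 1)) {
      dx <- m[i, j + 1] - m[i, j]
      dy <- m[i + 1, j] - m[i, j]
      ag <- ag + sqrt((dx^2 + dy^2) / 2)
    }
    ag <- ag / ((M - 1) * (N - 1))
    expect_equal(spatial_frequency(m, 1), sf, tolerance = 1e-9)
    expect_equal(average_gradient(m, 1), ag, tolerance = 1e-9)
  }
})

test_that("attention-selection carries more texture than plain averaging on complementary views", {
  sp <- tiny_synth_spec()
  cfg <- fusion_config()
  n <- 50L
  d_sf <- d_ag <- numeric(n)
  for (p in seq_len(n)) {
    sc <- synthetic_scene(sp, (p %% 3L) + 1L, 4000L + p)
    fa <- fuse_cams(sc$views, cfg, mode = "network", rule = "attention")$values
    fb <- fuse_cams(sc$views, cfg, mode = "network", rule = "average")$values
    d_sf[p] <- spatial_frequency(fa, 1) - spatial_frequency(fb, 1)
    d_ag[p] <- average_gradient(fa, 255) - average_gradient(fb, 255)
  }
  expect_lt(stats::binom.test(sum(d_sf > 0), n, alternative = "greater")$p.value,
            0.05)
  expect_lt(stats::binom.test(sum(d_ag > 0), n, alternative = "greater")$p.value,
            0.05)
  expect_gt(mean(d_sf), 0)
  expect_gt(mean(d_ag), 0)
})

test_that("classification reports compute macro metrics from the confusion matrix", {
  perf <- classification_report(c("a", "a", "b", "b"), c("a", "a", "b", "b"))
  expect_equal(perf$f1, 100)
  expect_equal(perf$accuracy, 100)

  yt <- c(rep("a", 4), rep("b", 4))
  yp <- c("a", "a", "a", "b", "b", "b", "b", "a")  # confusion [[3,1],[1,3]]
  r <- classification_report(yt, yp)
  expect_equal(r$accuracy, 75)
  expect_equal(r$f1, 75)
  expect_equal(unname(r$confusion), matrix(c(3, 1, 1, 3), 2))
  expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) / sum(r$confusion))

  # a single predicted class over two balanced true classes
  one <- classification_report(c("a", "a", "b", "b"), rep("a", 4))
  expect_equal(one$recall, 50)
  expect_equal(one$per_class$precision[one$per_class$class == "b"], 0)

  expect_error(classification_report(c("a", "b"), "a"), "same length")
  expect_error(classification_report(c("a", "a"), c("a", "a")), "2 classes")
})

test_that("reports tidy, glance and persist", {
  r <- classification_report(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$class, c("a", "b"))
  gl <- glance(r)
  expect_identical(names(gl), c("f1", "recall", "precision", "accuracy", "n"))
  expect_equal(gl$n, 4L)
  pre <- file.path(withr::local_tempdir(), "rep")
  write_report(r, pre)
  js <- jsonlite::read_json(paste0(pre, ".json"), simplifyVector = TRUE)
  expect_equal(js$accuracy, r$accuracy)
  expect_true(file.exists(paste0(pre, "_per_class.csv")))
  fm <- fusion_metrics(rand_map(6L, 6L, 3L))
  expect_identical(names(fm), c("sf", "ag", "scale"))
})
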