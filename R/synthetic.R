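# Synthetic fine-grained "insect" fixtures: a textured ellipse (the insect)
# on a textured background, with class identity carried by the ellipse's
# eccentricity, texture frequency and orientation -- subtle, whole-body cues,
# so recognition genuinely benefits from seeing more of the body.
#
# The complementary-view maps emulate the multi-view CAM structure the fusion
# stage is designed for: each of the three views highlights one 150-degree
# angular sector of the ellipse (sector centers 120 degrees apart), so every
# single view covers under 60% of the body while the union covers all of it.
# Fusion superiority on this task is a designed, testable consequence of that
# coverage geometry, not an empirical hope.

#' Synthetic dataset specification
#'
#' @param n_classes number of classes.
#' @param per_class images per class (>= 2).
#' @param image_side image edge in pixels (>= 32).
#' @param eccentricity range of class ellipse eccentricities.
#' @param fg_freq range of foreground (insect) texture frequencies,
#'   cycles per image.
#' @param bg_freq range of background texture frequencies.
#' @param noise_sd pixel Gaussian noise standard deviation.
#' @param complementary_views also generate the three per-view importance
#'   maps with complementary sector coverage.
#' @param sector_width angular width of each view's sector, degrees.
#' @param view_noise amplitude of the low-level background noise added to
#'   view maps.
#' @param seed integer master seed; everything downstream derives from it.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, per_class = 100L, image_side = 64L,
                           eccentricity = c(0.45, 0.8),
                           fg_freq = c(4, 9), bg_freq = c(1, 3),
                           noise_sd = 0.08, complementary_views = TRUE,
                           sector_width = 150, view_noise = 0.15,
                           seed = 1L) {
  stopifnot(per_class >= 2L, image_side >= 32L, n_classes >= 1L)
  structure(list(n_classes = as.integer(n_classes),
                 per_class = as.integer(per_class),
                 image_side = as.integer(image_side),
                 eccentricity = eccentricity, fg_freq = fg_freq,
                 bg_freq = bg_freq, noise_sd = noise_sd,
                 complementary_views = isTRUE(complementary_views),
                 sector_width = sector_width, view_noise = view_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Per-class appearance parameters, a deterministic function of the spec seed.
.class_params <- function(spec) {
  with_seed(spec$seed * 31L + 7L, {
    k <- spec$n_classes
    tibble::tibble(
      class = seq_len(k),
      ecc = stats::runif(k, spec$eccentricity[1], spec$eccentricity[2]),
      freq = stats::runif(k, spec$fg_freq[1], spec$fg_freq[2]),
      orient = stats::runif(k, 0, 180),
      phase_r = stats::runif(k, 0, 2 * pi),
      phase_g = stats::runif(k, 0, 2 * pi),
      phase_b = stats::runif(k, 0, 2 * pi))
  })
}

# Pixel-center coordinate grids (column-major: x = column, y = row).
.grids <- function(s) {
  list(x = matrix(rep(seq_len(s) - 0.5, each = s), s, s),
       y = matrix(rep(seq_len(s) - 0.5, times = s), s, s))
}

.sector_mask <- function(gx, gy, cx, cy, center_deg, width_deg) {
  ang <- atan2(gy - cy, gx - cx) * 180 / pi
  d <- (ang - center_deg + 180) %% 360 - 180
  abs(d) <= width_deg / 2
}

#' Generate one synthetic scene in memory
#'
#' One textured-ellipse image with its ground-truth mask and (when the spec
#' asks for them) the three complementary view maps. `sector_jitter` shifts
#' the three sector centers (in degrees) and is used to emulate view-specific
#' CAM perturbations in robustness experiments.
#'
#' @param spec a [synthetic_spec()].
#' @param class_id class index in `1..n_classes`.
#' @param scene_seed integer seed for this scene.
#' @param sector_jitter numeric length-3, degrees.
#' @return list with `image` (H x W x 3), `mask` (logical H x W), `views`
#'   (named list of three map matrices, or NULL) and `class`.
#' @export
synthetic_scene <- function(spec, class_id, scene_seed,
                            sector_jitter = c(0, 0, 0)) {
  cp <- .class_params(spec)[class_id, ]
  s <- spec$image_side
  g <- .grids(s)
  with_seed(scene_seed, {
    cx <- s / 2 + stats::runif(1, -0.06, 0.06) * s
    cy <- s / 2 + stats::runif(1, -0.06, 0.06) * s
    a <- 0.33 * s * stats::runif(1, 0.9, 1.1)
    b <- a * sqrt(1 - cp$ecc^2)
    phi <- (cp$orient + stats::runif(1, -15, 15)) * pi / 180
    xr <- (g$x - cx) * cos(phi) + (g$y - cy) * sin(phi)
    yr <- -(g$x - cx) * sin(phi) + (g$y - cy) * cos(phi)
    mask <- (xr / a)^2 + (yr / b)^2 <= 1
    # textures: oriented sinusoid gratings, class-dependent in the foreground
    tdir <- phi + pi / 5
    carrier <- 2 * pi * cp$freq * ((g$x * cos(tdir) + g$y * sin(tdir)) / s)
    bfreq <- mean(spec$bg_freq)
    bdir <- stats::runif(1, 0, pi)
    bcar <- 2 * pi * bfreq * ((g$x * cos(bdir) + g$y * sin(bdir)) / s) +
      stats::runif(1, 0, 2 * pi)
    img <- array(0, c(s, s, 3L))
    phases <- c(cp$phase_r, cp$phase_g, cp$phase_b)
    for (ch in 1:3) {
      fg <- 0.55 + 0.35 * sin(carrier + phases[ch])
      bg <- 0.45 + 0.22 * sin(bcar + (ch - 1) * pi / 3)
      plane <- bg
      plane[mask] <- fg[mask]
      img[, , ch] <- plane
    }
    img <- clip01(img + array(stats::rnorm(3 * s * s, 0, spec$noise_sd),
                              c(s, s, 3L)))
    views <- NULL
    if (spec$complementary_views) {
      phi0 <- stats::runif(1, 0, 360)
      centers <- phi0 + c(0, 120, 240) + sector_jitter
      views <- vector("list", 3L)
      names(views) <- c("cnn", "vit", "swin")
      for (i in 1:3) {
        sec <- mask & .sector_mask(g$x, g$y, cx, cy, centers[i],
                                   spec$sector_width)
        v <- gaussian_blur(matrix(as.numeric(sec), s, s), 5L)
        if (max(v) > 0) v <- v / max(v)
        noise <- matrix(stats::runif(s * s, 0, spec$view_noise), s, s)
        views[[i]] <- clip01(pmax(v, noise))
      }
    }
    list(image = img, mask = mask, views = views, class = class_id,
         center = c(cx, cy))
  })
}

.scene_seed <- function(spec, class_id, i)
  as.integer((abs(spec$seed) * 100003 + class_id * 1009 + i * 17) %% 2147483647)

#' Generate a synthetic dataset on disk
#'
#' Writes class-labelled 8-bit PNG images, ground-truth ellipse masks, and
#' (when `complementary_views`) three per-image importance maps (16-bit TIFF
#' + JSON sidecar, one per backbone view), plus a `manifest.csv`. Fully
#' deterministic: the same spec writes byte-identical files.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the manifest tibble: `image_id`, `path`, `label`, `mask_path`, and
#'   `map_cnn` / `map_vit` / `map_swin` when views are generated.
#' @export
synthetic_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (sub in c("images", "masks", if (spec$complementary_views) "maps"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  rows <- vector("list", spec$n_classes * spec$per_class)
  r <- 1L
  for (k in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$per_class)) {
      sc <- synthetic_scene(spec, k, .scene_seed(spec, k, i))
      id <- sprintf("cls%02d_im%04d", k, i)
      ip <- file.path(dir, "images", paste0(id, ".png"))
      mp <- file.path(dir, "masks", paste0(id, "_mask.png"))
      png::writePNG(sc$image, ip)
      png::writePNG(matrix(as.numeric(sc$mask), spec$image_side), mp)
      row <- tibble::tibble(image_id = id, path = ip,
                            label = paste0("class", k), mask_path = mp)
      if (spec$complementary_views) {
        for (src in names(sc$views)) {
          vp <- file.path(dir, "maps", paste0(id, "_", src, ".tif"))
          write_importance_map(
            importance_map(sc$views[[src]], source = src, image_id = id,
                           target_class = k), vp)
          row[[paste0("map_", src)]] <- vp
        }
      }
      rows[[r]] <- row
      r <- r + 1L
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a dataset manifest CSV
#' @param path path to a `manifest.csv` (or a directory containing one).
#' @return manifest tibble.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Generate paired original/perturbed scenes for robustness analysis
#'
#' Each pair holds one scene and a perturbed partner: the partner's image is
#' a rotated copy (reflection padding) and its three view maps are
#' regenerated with the sector centers jittered in complementary directions
#' (alternating signs across views, magnitudes around `jitter_deg`), emulating
#' how augmentation deviates each backbone's CAM differently. Both members'
#' maps live in the same (unrotated) frame so they are directly comparable.
#'
#' @param n_pairs number of pairs.
#' @param spec a [synthetic_spec()] (per_class is ignored here).
#' @param jitter_deg nominal sector jitter magnitude in degrees.
#' @param rotate_range rotation range in degrees for the partner image.
#' @param seed integer seed.
#' @return list of pairs; each pair is
#'   `list(class, original = list(image, views), augmented = list(image, views))`.
#' @export
make_robustness_pairs <- function(n_pairs = 50L, spec = synthetic_spec(),
                                  jitter_deg = 30, rotate_range = c(-45, 45),
                                  seed = 1L) {
  stopifnot(n_pairs >= 1L)
  pairs <- vector("list", n_pairs)
  draws <- with_seed(seed * 977L + 5L, tibble::tibble(
    class = sample.int(spec$n_classes, n_pairs, replace = TRUE),
    angle = stats::runif(n_pairs, rotate_range[1], rotate_range[2]),
    jmag = stats::runif(n_pairs, 0.7, 1.3) * jitter_deg))
  for (p in seq_len(n_pairs)) {
    ss <- as.integer((abs(seed) * 7717 + p * 271) %% 2147483647)
    orig <- synthetic_scene(spec, draws$class[p], ss)
    jit <- draws$jmag[p] * c(1, -1, 1)
    pert <- synthetic_scene(spec, draws$class[p], ss, sector_jitter = jit)
    pert$image <- clip01(warp_affine(pert$image, angle = draws$angle[p]))
    pairs[[p]] <- list(class = draws$class[p],
                       original = list(image = orig$image, views = orig$views),
                       augmented = list(image = pert$image, views = pert$views))
  }
  pairs
}
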