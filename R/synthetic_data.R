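#' Synthetic grain scenes (dead-leaves model)
#'
#' Grain images on a conveyor are scenes of many overlapping, locally
#' homogeneous particles. The generator emulates this with a dead-leaves
#' process: a Poisson number of ellipses with random centers, sizes,
#' orientations and gray levels is painted in sequence, later particles
#' occluding earlier ones; Gaussian sensor noise is added and intensities
#' clipped to [0, 1]. Derivative-response histograms of such scenes are
#' symmetric and heavy-tailed, the regime the WD model describes.
#'
#' @name synthetic_data
NULL

#' Grain-scene generator configuration
#'
#' @param height,width image size in pixels.
#' @param density expected number of particles per 1000 px^2.
#' @param mean_radius mean particle semi-minor radius in pixels.
#' @param radius_dispersion standard deviation of the radius (gamma
#'   distributed, truncated below at 0.5 px).
#' @param elongation semi-axis ratio >= 1 (1 = circular particles).
#' @param orientation particle long-axis angle in degrees, or `NULL` for
#'   independent uniform orientations per particle.
#' @param contrast_mean,contrast_sd mean and spread of per-particle gray
#'   levels.
#' @param background background gray level.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return A `grain_scene_config` list.
#' @export
grain_scene_config <- function(height = 96L, width = 96L, density = 6,
                               mean_radius = 4, radius_dispersion = 1.5,
                               elongation = 1, orientation = NULL,
                               contrast_mean = 0.55, contrast_sd = 0.15,
                               background = 0.2, noise_sd = 0.02,
                               seed = 1L) {
  if (height < 8L || width < 8L) stop("image too small")
  if (density < 0) stop("'density' must be >= 0")
  if (mean_radius <= 0 || radius_dispersion < 0) stop("invalid radius model")
  if (elongation < 1) stop("'elongation' must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 density = density, mean_radius = mean_radius,
                 radius_dispersion = radius_dispersion,
                 elongation = elongation, orientation = orientation,
                 contrast_mean = contrast_mean, contrast_sd = contrast_sd,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "grain_scene_config")
}

#' Generate one grain-scene image
#'
#' @param cfg a [grain_scene_config()].
#' @return `height x width` numeric matrix with values in [0, 1];
#'   reproducible for a fixed `cfg$seed`.
#' @export
generate_grain_image <- function(cfg) {
  stopifnot(inherits(cfg, "grain_scene_config"))
  with_seed(cfg$seed, {
    img <- matrix(cfg$background, cfg$height, cfg$width)
    ## centers fall in a padded region so edge coverage is unbiased; the
    ## Poisson intensity covers the padded area at the configured density
    pad <- (cfg$mean_radius + 4 * cfg$radius_dispersion) * cfg$elongation
    n_particles <- stats::rpois(
      1L, cfg$density * (cfg$height + 2 * pad) * (cfg$width + 2 * pad) / 1000)
    if (n_particles == 0L) {
      warning("zero particles drawn: background-only image")
    } else {
      cy <- stats::runif(n_particles, 1 - pad, cfg$height + pad)
      cx <- stats::runif(n_particles, 1 - pad, cfg$width + pad)
      if (cfg$radius_dispersion > 0) {
        shp <- (cfg$mean_radius / cfg$radius_dispersion)^2
        rad <- stats::rgamma(n_particles, shape = shp,
                             rate = shp / cfg$mean_radius)
      } else {
        rad <- rep(cfg$mean_radius, n_particles)
      }
      rad <- pmax(rad, 0.5)
      gray <- pmin(pmax(stats::rnorm(n_particles, cfg$contrast_mean,
                                     cfg$contrast_sd), 0), 1)
      ang <- if (is.null(cfg$orientation))
        stats::runif(n_particles, 0, 180) else rep(cfg$orientation, n_particles)
      for (k in seq_len(n_particles)) {
        a <- rad[k] * cfg$elongation   # semi-major, along `ang`
        b <- rad[k]
        th <- ang[k] * pi / 180
        r0 <- max(1L, floor(cy[k] - a)); r1 <- min(cfg$height, ceiling(cy[k] + a))
        c0 <- max(1L, floor(cx[k] - a)); c1 <- min(cfg$width, ceiling(cx[k] + a))
        if (r0 > r1 || c0 > c1) next
        yy <- r0:r1; xx <- c0:c1
        dy <- matrix(yy - cy[k], length(yy), length(xx))
        dx <- matrix(xx - cx[k], length(yy), length(xx), byrow = TRUE)
        u <- (dx * cos(th) + dy * sin(th)) / a
        v <- (-dx * sin(th) + dy * cos(th)) / b
        inside <- u * u + v * v <= 1
        block <- img[yy, xx, drop = FALSE]
        block[inside] <- gray[k]
        img[yy, xx] <- block
      }
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                          nrow(img), ncol(img))
    pmin(pmax(img, 0), 1)
  })
}

## Deterministic per-image seed, independent of generation order.
derive_seed <- function(master, class_index, i) {
  as.integer((as.numeric(master) * 7919 + class_index * 104729 + i * 263) %%
               2147483647)
}

#' Generate a labeled two-class image dataset
#'
#' Class A images are labeled +1, class B images -1 (the binary quality
#' convention: -1 = high quality, +1 = other). Per-image seeds are derived
#' deterministically from the master seed, so the dataset is reproducible
#' and order-independent.
#'
#' @param class_a,class_b [grain_scene_config()]s for the two classes
#'   (their own `seed` fields are ignored).
#' @param n_a,n_b images per class, >= 1.
#' @param seed master integer seed.
#' @return List with `images` (list of matrices) and `labels`
#'   (+1 for class A, -1 for class B).
#' @export
generate_labeled_dataset <- function(class_a, class_b, n_a, n_b, seed = 1L) {
  if (n_a < 1L || n_b < 1L) stop("need at least one image per class")
  make <- function(cfg, cls_idx, n, label) {
    lapply(seq_len(n), function(i) {
      cfg$seed <- derive_seed(seed, cls_idx, i)
      generate_grain_image(cfg)
    })
  }
  imgs <- c(make(class_a, 1L, n_a), make(class_b, 2L, n_b))
  list(images = imgs, labels = c(rep(1, n_a), rep(-1, n_b)))
}
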