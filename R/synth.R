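# Synthetic "object space" generator.
#
# Emulates the statistical structure the topographic analysis assumes of a
# rectified CNN embedding: a nonnegative high-dimensional point cloud whose
# dominant variance is spanned by two latent factors (animacy and real-world
# size), with per-category cluster structure and tight focal clusters
# (face-like, scene-like) nested inside the animate and inanimate zones.

#' Synthetic object-space configuration
#'
#' Defaults define the package's reference study conditions: 256 feature
#' dimensions; 14 regular categories assigned round-robin to the four
#' animacy-by-size cells plus two focal categories ("faces": animate/small,
#' "scenes": inanimate/big), 60 images each (960 samples); animacy and size
#' factor gains 4 and 3 on random orthonormal axes; category-centroid spread
#' 1; per-image isotropic noise sd 0.5; focal-cluster tightness 0.25; a
#' uniform nonnegative base level of 3 with rectification (negative entries
#' clipped to 0).
#'
#' @param feature_dim embedding dimensionality (>= 3).
#' @param images_per_category images drawn per category (>= 2).
#' @param n_regular_categories non-focal categories, spread round-robin over
#'   the animacy x size cells.
#' @param factor_gain_animacy,factor_gain_size projection of each category
#'   centroid onto the planted animacy/size axes (+gain for animate/big,
#'   -gain for inanimate/small).
#' @param category_spread sd of the isotropic category-centroid offset (per
#'   axis; equivalently the sd of the offset's projection on any direction).
#' @param image_noise_sd sd of per-image isotropic noise.
#' @param base_level uniform nonnegative offset added to every feature,
#'   keeping most entries positive under rectification.
#' @param focal_categories list of focal (tight) clusters; each element is a
#'   list with `label`, `animacy` (`"animate"`/`"inanimate"`), `size`
#'   (`"big"`/`"small"`), and `tightness` (centroid-offset sd, must be below
#'   `category_spread`).
#' @param nonneg_clip clip negative entries to zero (default TRUE).
#' @param seed integer seed.
#' @return An object of class `"synth_config"` (a validated list).
#' @export
synth_config <- function(feature_dim = 256,
                         images_per_category = 60,
                         n_regular_categories = 14,
                         factor_gain_animacy = 4,
                         factor_gain_size = 3,
                         category_spread = 1,
                         image_noise_sd = 0.5,
                         base_level = 3,
                         focal_categories = list(
                           list(label = "faces", animacy = "animate",
                                size = "small", tightness = 0.25),
                           list(label = "scenes", animacy = "inanimate",
                                size = "big", tightness = 0.25)),
                         nonneg_clip = TRUE,
                         seed = NULL) {
  if (feature_dim < 3L) stopf("feature_dim must be at least 3 (two planted axes plus noise)")
  if (images_per_category < 2L) stopf("need at least 2 images per category")
  if (factor_gain_animacy < 0 || factor_gain_size < 0) stopf("factor gains must be nonnegative")
  if (category_spread < 0 || image_noise_sd < 0) stopf("spreads and noise sds must be nonnegative")
  for (fc in focal_categories) {
    if (!all(c("label", "animacy", "size", "tightness") %in% names(fc)))
      stopf("each focal category needs label, animacy, size, tightness")
    if (!fc$animacy %in% c("animate", "inanimate") || !fc$size %in% c("big", "small"))
      stopf("focal category '%s' has unknown animacy/size values", fc$label)
    if (fc$tightness >= category_spread && category_spread > 0)
      stopf("focal tightness must be below category_spread")
  }
  structure(list(feature_dim = as.integer(feature_dim),
                 images_per_category = as.integer(images_per_category),
                 n_regular_categories = as.integer(n_regular_categories),
                 factor_gain_animacy = factor_gain_animacy,
                 factor_gain_size = factor_gain_size,
                 category_spread = category_spread,
                 image_noise_sd = image_noise_sd,
                 base_level = base_level,
                 focal_categories = focal_categories,
                 nonneg_clip = isTRUE(nonneg_clip),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  n_cat <- x$n_regular_categories + length(x$focal_categories)
  cat(sprintf("Synthetic object-space config: %d-D, %d categories x %d images = %d samples\n",
              x$feature_dim, n_cat, x$images_per_category,
              n_cat * x$images_per_category))
  cat(sprintf("  gains: animacy %g, size %g; spread %g, noise %g, base %g, clip %s\n",
              x$factor_gain_animacy, x$factor_gain_size, x$category_spread,
              x$image_noise_sd, x$base_level, x$nonneg_clip))
  invisible(x)
}

# Internal: random orthonormal pair in feature_dim dimensions.
random_orthonormal_pair <- function(feature_dim) {
  q <- qr.Q(qr(matrix(rnorm(feature_dim * 2L), feature_dim, 2L)))
  list(u1 = q[, 1], u2 = q[, 2])
}

#' Generate a synthetic object space
#'
#' Draws a nonnegative feature matrix plus label table with planted animacy
#' and real-world-size axes. Two random orthonormal directions `u_anim`,
#' `u_size` span the latent factor plane; each category centroid is
#' `base + a_c * g_a * u_anim + s_c * g_s * u_size + offset` with signs
#' `a_c, s_c` taken from its animacy/size attributes and an isotropic
#' centroid offset (sd `category_spread`; focal categories use their tighter
#' `tightness` instead). Each image is its category centroid plus isotropic
#' noise; negative entries are then clipped to 0 if `nonneg_clip`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; overrides `config$seed` when given.
#' @return A list with `features` (n x F matrix, image ids as row names),
#'   `labels` (data frame: `image_id`, `category`, `animacy`, `size`,
#'   `split`), `axes` (the planted `u_animacy`, `u_size` directions and the
#'   per-category centroids), and the echoed `config`.
#' @examples
#' os <- generate_object_space(synth_config(feature_dim = 32,
#'                                          images_per_category = 5), seed = 1)
#' table(os$labels$animacy, os$labels$size)
#' @export
generate_object_space <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(seed) && !is.na(config$seed)) seed <- config$seed
  # cell order chosen so that the default 14 regular categories split 7/7 on
  # each factor once the two focal categories (one animate, one inanimate;
  # one big, one small) are added
  cells <- data.frame(animacy = c("animate", "inanimate", "inanimate", "animate"),
                      size = c("big", "small", "big", "small"))
  n_reg <- config$n_regular_categories
  reg <- cells[((seq_len(n_reg) - 1L) %% 4L) + 1L, , drop = FALSE]
  reg$label <- sprintf("%s_%s_%02d", substr(reg$animacy, 1, 4), reg$size,
                       seq_len(n_reg))
  reg$tightness <- config$category_spread
  foc <- do.call(rbind, lapply(config$focal_categories, function(fc)
    data.frame(animacy = fc$animacy, size = fc$size, label = fc$label,
               tightness = fc$tightness)))
  cats <- rbind(reg, foc)
  rownames(cats) <- NULL

  out <- with_seed_if(seed, {
    axes <- random_orthonormal_pair(config$feature_dim)
    Fd <- config$feature_dim
    base <- rep(config$base_level, Fd)
    centroids <- t(vapply(seq_len(nrow(cats)), function(i) {
      a <- if (cats$animacy[i] == "animate") 1 else -1
      s <- if (cats$size[i] == "big") 1 else -1
      base + a * config$factor_gain_animacy * axes$u1 +
        s * config$factor_gain_size * axes$u2 +
        rnorm(Fd, 0, cats$tightness[i])
    }, numeric(Fd)))
    m <- config$images_per_category
    feats <- matrix(NA_real_, nrow(cats) * m, Fd)
    for (i in seq_len(nrow(cats))) {
      rows <- (i - 1L) * m + seq_len(m)
      feats[rows, ] <- matrix(centroids[i, ], m, Fd, byrow = TRUE) +
        matrix(rnorm(m * Fd, 0, config$image_noise_sd), m, Fd)
    }
    if (config$nonneg_clip) feats[feats < 0] <- 0
    list(axes = axes, centroids = centroids, feats = feats)
  })

  m <- config$images_per_category
  labels <- data.frame(
    image_id = sprintf("%s_img%03d", rep(cats$label, each = m),
                       rep(seq_len(m), times = nrow(cats))),
    category = rep(cats$label, each = m),
    animacy = rep(cats$animacy, each = m),
    size = rep(cats$size, each = m),
    split = "train",
    stringsAsFactors = FALSE)
  rownames(out$feats) <- labels$image_id
  rownames(out$centroids) <- cats$label
  list(features = out$feats, labels = labels,
       axes = list(u_animacy = out$axes$u1, u_size = out$axes$u2,
                   centroids = out$centroids),
       config = config)
}

#' Generate a planar manifold embedded in high dimensions
#'
#' Test fixture for topographic-ordering checks: points uniform on a 2D
#' rectangle, embedded into `feature_dim` dimensions by a random orthonormal
#' pair, plus optional tiny isotropic jitter. With zero jitter the point
#' cloud is exactly rank 2 about its mean.
#'
#' @param n_points number of points (>= 16).
#' @param feature_dim embedding dimensionality (>= 2).
#' @param extent rectangle side lengths, `c(width, height)`.
#' @param jitter_sd sd of isotropic off-plane jitter (default 0).
#' @param seed integer seed.
#' @return An `n_points` x `feature_dim` matrix with row names `pt0001`...;
#'   the embedding basis is attached as attribute `"basis"`.
#' @export
generate_planar_manifold <- function(n_points, feature_dim = 64,
                                     extent = c(1, 1), jitter_sd = 0,
                                     seed = NULL) {
  if (n_points < 16L) stopf("n_points must be at least 16")
  if (feature_dim < 2L) stopf("feature_dim must be at least 2")
  with_seed_if(seed, {
    uv <- cbind(runif(n_points, -extent[1] / 2, extent[1] / 2),
                runif(n_points, -extent[2] / 2, extent[2] / 2))
    basis <- qr.Q(qr(matrix(rnorm(feature_dim * 2L), feature_dim, 2L)))
    x <- uv %*% t(basis)
    if (jitter_sd > 0)
      x <- x + matrix(rnorm(n_points * feature_dim, 0, jitter_sd),
                      n_points, feature_dim)
    rownames(x) <- sprintf("pt%04d", seq_len(n_points))
    attr(x, "basis") <- basis
    x
  })
}
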