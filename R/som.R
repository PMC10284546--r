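#' Principal plane of a feature sample
#'
#' Computes the sample mean and the top two eigenvectors/eigenvalues of the
#' covariance of a feature sample. The plane spanned by the two eigenvectors,
#' scaled by the square roots of the eigenvalues, is used to shape and
#' initialize the map grid.
#'
#' @param x numeric matrix (samples x features), at least 3 rows and 2
#'   columns, all finite.
#' @return An object of class `"principal_plane"`: a list with `mean`
#'   (feature-space mean), `vectors` (features x 2, unit-norm, orthogonal),
#'   and `values` (the two leading eigenvalues, `values[1] >= values[2]`).
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' principal_plane(x)
#' @export
principal_plane <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stopf("need at least 3 samples to estimate the principal plane")
  if (ncol(x) < 2L) stopf("need at least 2 feature dimensions")
  if (!all(is.finite(x))) stopf("feature matrix contains non-finite values")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  if (sum(xc^2) == 0) stopf("degenerate sample: zero total variance")
  sv <- svd(xc, nu = 0L, nv = 2L)
  values <- sv$d[1:2]^2 / (nrow(x) - 1L)
  vectors <- sv$v
  if (ncol(vectors) < 2L) { # rank-1 input: pad an arbitrary orthogonal direction
    v2 <- rep(0, ncol(x))
    v2[[which.min(abs(vectors[, 1]))]] <- 1
    v2 <- v2 - sum(v2 * vectors[, 1]) * vectors[, 1]
    vectors <- cbind(vectors, v2 / sqrt(sum(v2^2)))
    values <- c(values[1], 0)
  }
  structure(list(mean = mu, vectors = vectors, values = values),
            class = "principal_plane")
}

#' @export
print.principal_plane <- function(x, ...) {
  cat("Principal plane:", length(x$mean), "feature dimensions\n")
  cat(sprintf("  eigenvalues: %.4g, %.4g (sqrt ratio %.3f)\n",
              x$values[1], x$values[2],
              sqrt(x$values[1] / max(x$values[2], .Machine$double.xmin))))
  invisible(x)
}

#' Choose a map grid shape from the data aspect ratio
#'
#' Picks grid dimensions `(W, H)` whose product is close to the requested
#' number of units and whose aspect ratio `W/H` matches the data's aspect on
#' the principal plane, `sqrt(values[1]) / sqrt(values[2])` (grid axes are
#' scaled by the square roots of the eigenvalues at initialization).
#'
#' Candidate factor pairs with both sides >= 2 and a unit count within 25% of
#' the request (the closest attainable count is always included) are ranked
#' by aspect mismatch `|log(W/H) - log(aspect)|`, then by `|W*H - n|`, then
#' toward the squarer shape.
#'
#' @param n_units requested number of map units (>= 4).
#' @param plane a [principal_plane()] object, or a numeric length-2 vector of
#'   eigenvalues.
#' @return Integer vector `c(W, H)` with `W >= H` when the aspect is >= 1.
#' @examples
#' choose_grid_shape(400, c(1, 1)) # 20 x 20
#' @export
choose_grid_shape <- function(n_units, plane) {
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 4L) stopf("n_units must be at least 4")
  values <- if (inherits(plane, "principal_plane")) plane$values else as.numeric(plane)
  if (values[2] <= 0) values[2] <- .Machine$double.eps * max(values[1], 1)
  aspect <- sqrt(values[1] / values[2])

  W <- rep(seq_len(n_units), each = n_units)
  H <- rep(seq_len(n_units), times = n_units)
  keep <- W >= 2L & H >= 2L & W * H <= ceiling(1.25 * n_units)
  W <- W[keep]; H <- H[keep]
  prod_err <- abs(W * H - n_units)
  band <- W * H >= floor(0.75 * n_units) | prod_err == min(prod_err)
  W <- W[band]; H <- H[band]; prod_err <- prod_err[band]
  aspect_err <- abs(log(W / H) - log(aspect))
  square_err <- abs(log(W / H))
  best <- order(round(aspect_err, 12), prod_err, round(square_err, 12), W)[1]
  c(W = W[best], H = H[best])
}

#' Learning-rate schedule
#'
#' Linear decay of the learning rate over epochs: `L_t = L0 * (1 - t / T)`,
#' with `t` the 0-based epoch index. The default initial rate is 0.3.
#'
#' @param t epoch index (0-based), `0 <= t < epochs`; may be a vector.
#' @param learning_rate initial rate `L0` in (0, 1].
#' @param epochs total number of epochs `T`.
#' @return The learning rate(s) at epoch `t`; strictly positive for `t < T`.
#' @export
som_learning_rate <- function(t, learning_rate = 0.3, epochs = 100) {
  if (any(t < 0) || any(t >= epochs)) stopf("epoch index t must satisfy 0 <= t < epochs")
  learning_rate * (1 - t / epochs)
}

#' Neighborhood-radius schedule
#'
#' Default linear decay `sigma_t = max(sigma0 * (1 - t/T), floor)`. The
#' `"exponential"` variant decays geometrically from `sigma0` to
#' `min(sigma0, 1)` over the run, `sigma_t = sigma0 * (min(sigma0,1)/sigma0)^(t/T)`,
#' floored the same way.
#'
#' @inheritParams som_learning_rate
#' @param sigma0 initial radius (grid units); conventionally half the larger
#'   grid dimension.
#' @param floor small positive lower bound preventing a zero radius.
#' @param schedule `"linear"` (default) or `"exponential"`.
#' @return The radius at epoch `t`, never below `floor`.
#' @export
som_radius <- function(t, sigma0, epochs = 100, floor = 1e-6,
                       schedule = c("linear", "exponential")) {
  schedule <- match.arg(schedule)
  if (any(t < 0) || any(t >= epochs)) stopf("epoch index t must satisfy 0 <= t < epochs")
  if (sigma0 <= 0) stopf("sigma0 must be positive")
  s <- if (schedule == "linear") {
    sigma0 * (1 - t / epochs)
  } else {
    sigma0 * (min(sigma0, 1) / sigma0)^(t / epochs)
  }
  pmax(s, floor)
}

#' Euclidean distance between map units on the grid
#'
#' Distances are measured directly on the 2D grid in unit steps,
#' `sqrt((w_a - w_b)^2 + (h_a - h_b)^2)`, never in feature space.
#'
#' @param unit_a,unit_b length-2 vectors `(w, h)` of 0-based grid
#'   coordinates, or matrices with one `(w, h)` row per unit.
#' @return Numeric distance(s).
#' @export
grid_distance <- function(unit_a, unit_b) {
  a <- if (is.matrix(unit_a)) unit_a else matrix(unit_a, ncol = 2)
  b <- if (is.matrix(unit_b)) unit_b else matrix(unit_b, ncol = 2)
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

#' Gaussian neighborhood weight
#'
#' The influence of a BMU on another map unit:
#' `exp(-d^2 / (2 * sigma^2))` with `d` the grid distance between them.
#' Equals 1 exactly when `unit` is the BMU.
#'
#' @param bmu,unit length-2 `(w, h)` grid coordinates (matrices of rows
#'   allowed for `unit`).
#' @param sigma positive neighborhood radius.
#' @return Weight(s) in (0, 1].
#' @export
neighborhood_weight <- function(bmu, unit, sigma) {
  if (sigma <= 0) stopf("sigma must be positive")
  d <- grid_distance(matrix(bmu, ncol = 2)[rep(1L, if (is.matrix(unit)) nrow(unit) else 1L), , drop = FALSE],
                     unit)
  exp(-d^2 / (2 * sigma^2))
}

# Internal: exact per-row BMU with explicit squared distances; ties fall to
# the smallest row-major unit index (which.min semantics). O(n U F).
bmu_index_exact <- function(codebook, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != ncol(codebook)) stopf("feature dimension mismatch: input has %d, codebook has %d",
                                       ncol(x), ncol(codebook))
  vapply(seq_len(nrow(x)), function(i) {
    d2 <- rowSums(sweep(codebook, 2L, x[i, ])^2)
    which.min(d2)
  }, integer(1))
}

#' Best matching unit
#'
#' Finds, for each input vector, the map unit whose tuning vector has the
#' minimum Euclidean distance to it. Ties are broken toward the smallest
#' row-major unit index.
#'
#' @param object a fitted [som()] object.
#' @param x a feature vector of length F, or an n x F matrix.
#' @return A data frame with one row per input: 0-based row-major `unit`
#'   index, grid coordinates `w`, `h`, and the Euclidean `distance` to the
#'   BMU tuning vector.
#' @export
find_bmu <- function(object, x) {
  stopifnot(inherits(object, "som"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  idx <- bmu_index_exact(object$codebook, x)
  d <- sqrt(rowSums((x - object$codebook[idx, , drop = FALSE])^2))
  co <- grid_coords(object$grid[1], object$grid[2])
  data.frame(unit = idx - 1L, w = co[idx, 1], h = co[idx, 2], distance = d)
}

#' Single-image codebook update
#'
#' Applies one competitive update: every unit's tuning vector moves toward
#' the input by `L_t * eta` of the remaining gap, where `eta` is the
#' Gaussian neighborhood weight of the unit relative to the BMU. The BMU
#' itself moves by exactly `L_t` of its gap; no unit overshoots the input.
#'
#' @param codebook U x F tuning matrix, units in row-major grid order.
#' @param x input feature vector of length F.
#' @param bmu length-2 `(w, h)` 0-based coordinates of the best matching unit.
#' @param learning_rate step size `L_t` in (0, 1].
#' @param sigma positive neighborhood radius.
#' @param grid length-2 `c(W, H)` grid shape.
#' @return The updated U x F codebook matrix.
#' @export
som_update <- function(codebook, x, bmu, learning_rate, sigma, grid) {
  if (length(x) != ncol(codebook)) stopf("feature dimension mismatch")
  if (learning_rate <= 0 || learning_rate > 1) stopf("learning_rate must be in (0, 1]")
  if (sigma <= 0) stopf("sigma must be positive")
  co <- grid_coords(grid[1], grid[2])
  eta <- exp(-grid_distance(co, matrix(bmu, ncol = 2)[rep(1L, nrow(co)), ])^2 / (2 * sigma^2))
  codebook + (learning_rate * eta) * (matrix(x, nrow(codebook), length(x), byrow = TRUE) - codebook)
}

#' Fit a self-organizing map
#'
#' Trains a 2D Kohonen map over a feature matrix. The codebook is
#' initialized as a regular lattice on the sample principal plane (grid axes
#' along the top two eigenvectors, scaled by the square roots of their
#' eigenvalues, spanning \[-1, 1\] around the data mean), with the grid shape
#' chosen from the eigenvalue aspect ratio. Training then runs `epochs`
#' passes over the data in batches: for each batch the best matching units
#' are found against the codebook state at the start of the batch, and the
#' per-image updates are applied sequentially in batch order with that
#' epoch's learning rate and neighborhood radius. Both schedules decay
#' linearly by default.
#'
#' @param x numeric feature matrix (samples x features), finite; row names
#'   are used as sample ids if present.
#' @param n_units requested number of map units (default 400); the realized
#'   grid is shaped by [choose_grid_shape()].
#' @param grid optional explicit `c(W, H)` grid shape, overriding `n_units`.
#' @param epochs total training epochs `T` (default 100).
#' @param learning_rate initial learning rate `L0` in (0, 1] (default 0.3).
#' @param radius initial neighborhood radius `sigma0`, or `"auto"` (half the
#'   larger grid dimension).
#' @param radius_schedule `"linear"` (default) or `"exponential"` decay.
#' @param radius_floor lower bound on the radius (default 1e-6).
#' @param batch_size images per batch (default 32).
#' @param init_sample_size number of rows sampled (without replacement) for
#'   the principal-plane estimate (default 400, capped at `nrow(x)`).
#' @param shuffle reshuffle the presentation order each epoch (default TRUE).
#' @param keep_data store `x` in the fit for later diagnostics (default TRUE).
#' @param seed integer seed making the fit fully reproducible; `NULL` uses
#'   the current RNG stream.
#' @return An object of class `"som"`: a list with `codebook` (U x F, units
#'   in row-major grid order), `grid` (`c(W, H)`), `coords` (U x 2, 0-based
#'   `(w, h)`), `trace` (per-epoch `qe`, `learning_rate`, `radius`, plus
#'   `qe_initial`), `plane`, `config`, and (optionally) `data`.
#' @seealso [predict.som()], [quantization_error()], [similarity_by_distance()]
#' @examples
#' x <- generate_planar_manifold(200, feature_dim = 8, seed = 1)
#' fit <- som(x, grid = c(6, 6), epochs = 5, init_sample_size = 100, seed = 1)
#' fit
#' @export
som <- function(x, n_units = 400, grid = NULL, epochs = 100,
                learning_rate = 0.3, radius = "auto",
                radius_schedule = c("linear", "exponential"),
                radius_floor = 1e-6, batch_size = 32,
                init_sample_size = 400, shuffle = TRUE,
                keep_data = TRUE, seed = NULL) {
  radius_schedule <- match.arg(radius_schedule)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stopf("empty feature matrix")
  if (!all(is.finite(x))) stopf("feature matrix contains non-finite values")
  if (epochs < 1L) stopf("epochs must be at least 1")
  if (learning_rate <= 0 || learning_rate > 1) stopf("learning_rate must be in (0, 1]")
  if (batch_size < 1L) stopf("batch_size must be at least 1")
  if (init_sample_size < 3L) stopf("init_sample_size must be at least 3")
  if (radius_floor <= 0) stopf("radius_floor must be positive")
  n <- nrow(x)

  fit <- with_seed_if(seed, {
    m <- min(init_sample_size, n)
    init_rows <- if (m < n) sort(sample.int(n, m)) else seq_len(n)
    plane <- principal_plane(x[init_rows, , drop = FALSE])
    gdim <- if (is.null(grid)) choose_grid_shape(n_units, plane)
            else c(W = as.integer(grid[1]), H = as.integer(grid[2]))
    W <- gdim[[1]]; H <- gdim[[2]]
    cb0 <- init_codebook_on_plane(plane, W, H)
    sigma0 <- if (identical(radius, "auto")) max(W, H) / 2 else as.numeric(radius)
    if (sigma0 <= 0) stopf("radius must be positive")
    ord <- vapply(seq_len(epochs), function(t) {
      if (shuffle) sample.int(n) else seq_len(n)
    }, integer(n))
    res <- .som_train_cpp(t(x), t(cb0), W, H, ord, as.integer(batch_size),
                          learning_rate, sigma0,
                          as.integer(radius_schedule == "exponential"),
                          radius_floor)
    list(plane = plane, W = W, H = H, cb0 = cb0, sigma0 = sigma0, res = res)
  })

  structure(list(
    codebook = t(fit$res$codebook_t),
    grid = c(W = fit$W, H = fit$H),
    coords = grid_coords(fit$W, fit$H),
    trace = list(qe = fit$res$qe, qe_initial = fit$res$qe_initial,
                 learning_rate = fit$res$learning_rate,
                 radius = fit$res$radius),
    plane = fit$plane,
    config = list(n_units = fit$W * fit$H, grid = c(fit$W, fit$H),
                  epochs = epochs, learning_rate = learning_rate,
                  radius = fit$sigma0, radius_schedule = radius_schedule,
                  radius_floor = radius_floor, batch_size = batch_size,
                  init_sample_size = init_sample_size, shuffle = shuffle,
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    n_samples = n,
    data = if (keep_data) x else NULL,
    call = match.call()
  ), class = "som")
}

# Internal: lattice initialization on the principal plane. Unit (w, h) gets
# mean + a_w sqrt(l1) v1 + b_h sqrt(l2) v2 with a, b linearly spaced on [-1, 1].
init_codebook_on_plane <- function(plane, W, H) {
  a <- if (W == 1L) 0 else seq(-1, 1, length.out = W)
  b <- if (H == 1L) 0 else seq(-1, 1, length.out = H)
  co <- grid_coords(W, H)
  s1 <- sqrt(plane$values[1]); s2 <- sqrt(plane$values[2])
  outer(rep(1, W * H), plane$mean) +
    (a[co[, 1] + 1L] * s1) %o% plane$vectors[, 1] +
    (b[co[, 2] + 1L] * s2) %o% plane$vectors[, 2]
}

#' Quantization error of a map
#'
#' Mean Euclidean distance between samples and the tuning vectors of their
#' best matching units — the standard measure of how well the codebook fits
#' the data manifold.
#'
#' @param object a fitted [som()] object (or a plain U x F codebook matrix).
#' @param x feature matrix; defaults to the training data stored in the fit.
#' @return A nonnegative scalar.
#' @export
quantization_error <- function(object, x = NULL) {
  cb <- if (inherits(object, "som")) object$codebook else as.matrix(object)
  if (is.null(x)) {
    if (!inherits(object, "som") || is.null(object$data))
      stopf("no data stored in the fit; supply x")
    x <- object$data
  }
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (nrow(x) == 0L) stopf("empty feature matrix")
  .som_qe_cpp(t(cb), t(x))
}

#' Pairwise tuning similarity as a function of grid distance
#'
#' For every pair of map units, computes the Pearson correlation of their
#' tuning vectors and bins pairs by their grid distance (bins centered on
#' integers; the zero-distance self-pairs are excluded). A smoothly trained
#' map shows similarity falling off with distance.
#'
#' @param object a fitted [som()] object.
#' @return A data frame with `distance` (bin center), `similarity` (mean
#'   pairwise correlation in the bin), and `n` (pair count); pairs involving
#'   a constant (zero-variance) tuning vector are excluded and counted in
#'   the `"n_excluded"` attribute.
#' @export
similarity_by_distance <- function(object) {
  stopifnot(inherits(object, "som"))
  cb <- object$codebook
  U <- nrow(cb)
  if (U < 2L) stopf("need at least 2 units")
  sds <- apply(cb, 1L, sd)
  ok <- sds > 0
  co <- object$coords
  pair <- which(upper.tri(matrix(0, U, U)), arr.ind = TRUE)
  keep <- ok[pair[, 1]] & ok[pair[, 2]]
  n_excluded <- sum(!keep)
  pair <- pair[keep, , drop = FALSE]
  d <- grid_distance(co[pair[, 1], , drop = FALSE], co[pair[, 2], , drop = FALSE])
  cc <- cor(t(cb[ok, , drop = FALSE]))
  # remap pair indices into the ok-subset correlation matrix
  idx_ok <- cumsum(ok)
  r <- cc[cbind(idx_ok[pair[, 1]], idx_ok[pair[, 2]])]
  bin <- round(d)
  agg <- tapply(r, bin, mean)
  cnt <- tapply(r, bin, length)
  out <- data.frame(distance = as.numeric(names(agg)),
                    similarity = as.numeric(agg),
                    n = as.integer(cnt))
  out <- out[out$distance > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
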