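#' @export
print.som <- function(x, ...) {
  cat(sprintf("Self-organizing map: %d x %d grid (%d units), %d feature dimensions\n",
              x$grid[1], x$grid[2], prod(x$grid), ncol(x$codebook)))
  cat(sprintf("  trained %d epochs on %d samples (batch %d, L0 = %g, sigma0 = %g, %s radius)\n",
              x$config$epochs, x$n_samples, x$config$batch_size,
              x$config$learning_rate, x$config$radius, x$config$radius_schedule))
  cat(sprintf("  quantization error: %.4g (initial %.4g, ratio %.3f)\n",
              tail(x$trace$qe, 1), x$trace$qe_initial,
              tail(x$trace$qe, 1) / x$trace$qe_initial))
  invisible(x)
}

#' @export
summary.som <- function(object, ...) {
  qe <- object$trace$qe
  structure(list(
    grid = object$grid,
    feature_dim = ncol(object$codebook),
    n_samples = object$n_samples,
    config = object$config,
    qe_initial = object$trace$qe_initial,
    qe_final = tail(qe, 1),
    qe_ratio = tail(qe, 1) / object$trace$qe_initial,
    eigenvalues = object$plane$values,
    schedule_range = list(learning_rate = range(object$trace$learning_rate),
                          radius = range(object$trace$radius))
  ), class = "summary.som")
}

#' @export
print.summary.som <- function(x, ...) {
  cat(sprintf("Self-organizing map fit\n  grid: %d x %d, feature dim %d, %d training samples\n",
              x$grid[1], x$grid[2], x$feature_dim, x$n_samples))
  cat(sprintf("  principal-plane eigenvalues: %.4g, %.4g\n",
              x$eigenvalues[1], x$eigenvalues[2]))
  cat(sprintf("  epochs: %d, batch %d, L0 %g -> %.4g, sigma %g -> %.4g\n",
              x$config$epochs, x$config$batch_size,
              x$schedule_range$learning_rate[2], x$schedule_range$learning_rate[1],
              x$schedule_range$radius[2], x$schedule_range$radius[1]))
  cat(sprintf("  quantization error: %.4g -> %.4g (ratio %.3f)\n",
              x$qe_initial, x$qe_final, x$qe_ratio))
  invisible(x)
}

#' @export
coef.som <- function(object, ...) object$codebook

#' Predict method for self-organizing maps
#'
#' @param object a fitted [som()] object.
#' @param newdata feature matrix (or single vector); defaults to the stored
#'   training data.
#' @param type `"bmu"` returns the best-matching-unit assignment per sample
#'   (as [find_bmu()]); `"activation"` returns the n x U matrix of dot-product
#'   activations of every map unit to every sample.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.som <- function(object, newdata = NULL, type = c("bmu", "activation"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$data)) stopf("no data stored in the fit; supply newdata")
    newdata <- object$data
  }
  newdata <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  switch(type,
         bmu = find_bmu(object, newdata),
         activation = som_activations(object, newdata))
}

#' @export
fitted.som <- function(object, ...) {
  if (is.null(object$data)) stopf("no data stored in the fit")
  idx <- bmu_index_exact(object$codebook, object$data)
  f <- object$codebook[idx, , drop = FALSE]
  rownames(f) <- rownames(object$data)
  f
}

#' @export
residuals.som <- function(object, ...) {
  if (is.null(object$data)) stopf("no data stored in the fit")
  object$data - fitted(object)
}

#' Diagnostic plots for a fitted map
#'
#' @param x a fitted [som()] object.
#' @param type `"qe"` plots the quantization-error training curve;
#'   `"similarity"` the pairwise tuning similarity against grid distance;
#'   `"counts"` an image of per-unit BMU counts over the training data.
#' @param ... passed to the underlying plotting function.
#' @export
plot.som <- function(x, type = c("qe", "similarity", "counts"), ...) {
  type <- match.arg(type)
  if (type == "qe") {
    qe <- c(x$trace$qe_initial, x$trace$qe)
    graphics::plot(seq_along(qe) - 1L, qe, type = "l", xlab = "epoch",
                   ylab = "quantization error", main = "Map fit over training", ...)
  } else if (type == "similarity") {
    s <- similarity_by_distance(x)
    graphics::plot(s$distance, s$similarity, type = "b", xlab = "grid distance",
                   ylab = "mean tuning correlation",
                   main = "Tuning similarity vs map distance", ...)
  } else {
    if (is.null(x$data)) stopf("no data stored in the fit")
    idx <- bmu_index_exact(x$codebook, x$data)
    counts <- tabulate(idx, nbins = prod(x$grid))
    image_grid(unit_to_grid(counts, x$grid), main = "BMU counts", ...)
  }
  invisible(x)
}

# Internal: draw a W x H grid matrix with w increasing downward.
image_grid <- function(grid, main = "", zlim = NULL, col = NULL, ...) {
  W <- nrow(grid); H <- ncol(grid)
  if (is.null(col)) col <- grDevices::hcl.colors(64, "viridis")
  if (is.null(zlim)) zlim <- range(grid, finite = TRUE)
  z <- pmin(pmax(grid, zlim[1]), zlim[2])
  graphics::image(x = seq_len(H) - 1L, y = seq_len(W) - 1L, z = t(z[W:1, , drop = FALSE]),
                  zlim = zlim, col = col, xlab = "h", ylab = "w (top = 0)",
                  main = main, useRaster = TRUE, axes = FALSE, ...)
  graphics::axis(1); graphics::axis(2, at = seq_len(W) - 1L, labels = rev(seq_len(W) - 1L))
  invisible(NULL)
}
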