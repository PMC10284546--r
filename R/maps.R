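# Spatial activation, preference, and selectivity maps over a trained map.
#
# Activations treat each unit's tuning vector as a linear filter: the
# response of unit (w, h) to an input is the raw dot product of its tuning
# vector with the input's feature vector — no centering or normalization.

# Internal: n x U activation matrix (samples in rows, units row-major).
som_activations <- function(object, x) {
  cb <- if (inherits(object, "som")) object$codebook else as.matrix(object)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != ncol(cb)) stopf("feature dimension mismatch: input has %d, codebook has %d",
                                 ncol(x), ncol(cb))
  a <- tcrossprod(x, cb)
  rownames(a) <- rownames(x)
  a
}

#' Spatial activation map of one input
#'
#' The simulated response of every map unit to a single input: the dot
#' product of the unit's tuning vector with the input's feature vector.
#'
#' @param object a fitted [som()] object.
#' @param x feature vector of length F.
#' @return A W x H numeric matrix (rows are grid rows `w`, top row `w = 0`).
#' @export
activation_map <- function(object, x) {
  stopifnot(inherits(object, "som"))
  if (is.matrix(x) && nrow(x) != 1L) stopf("activation_map takes a single input vector; see predict(type = \"activation\")")
  unit_to_grid(drop(som_activations(object, x)), object$grid)
}

# Internal: validate labels against sample ids and return the grouping
# vector aligned to the rows of x.
aligned_labels <- function(x, labels, grouping) {
  if (!grouping %in% names(labels)) stopf("labels have no column '%s'", grouping)
  ids <- rownames(x)
  if (is.null(ids)) {
    if (nrow(labels) != nrow(x)) stopf("unlabelled feature matrix rows: %d features vs %d labels",
                                       nrow(x), nrow(labels))
    return(as.character(labels[[grouping]]))
  }
  miss <- setdiff(ids, as.character(labels$image_id))
  if (length(miss) > 0)
    stopf("samples missing from the label table: %s", paste(miss, collapse = ", "))
  as.character(labels[[grouping]][match(ids, as.character(labels$image_id))])
}

#' Per-condition activation statistics
#'
#' Computes, for every map unit and every level of a grouping attribute, the
#' mean and (unbiased, n-1) variance of the unit's activations across the
#' images of that condition.
#'
#' @param object a fitted [som()] object.
#' @param x probe feature matrix (samples x features) with row-name ids.
#' @param labels data frame with `image_id` plus attribute columns (e.g.
#'   `category`, `animacy`, `size`).
#' @param grouping name of the label column defining the conditions.
#' @return An object of class `"condition_stats"`: list with `mean` and
#'   `var` (U x C matrices, units row-major), `n` (images per condition),
#'   `conditions`, `grouping`, `grid`.
#' @export
condition_stats <- function(object, x, labels, grouping = "category") {
  stopifnot(inherits(object, "som"))
  g <- aligned_labels(x, labels, grouping)
  conditions <- if (is.factor(labels[[grouping]])) levels(labels[[grouping]]) else unique(g)
  conditions <- conditions[conditions %in% g]
  n_per <- vapply(conditions, function(cc) sum(g == cc), integer(1))
  if (any(n_per < 2L))
    stopf("condition '%s' has fewer than 2 images; variance undefined",
          conditions[which(n_per < 2L)[1]])
  a <- som_activations(object, x)
  mu <- vapply(conditions, function(cc) colMeans(a[g == cc, , drop = FALSE]),
               numeric(ncol(a)))
  vv <- vapply(conditions, function(cc) apply(a[g == cc, , drop = FALSE], 2L, var),
               numeric(ncol(a)))
  structure(list(mean = mu, var = vv, n = n_per, conditions = conditions,
                 grouping = grouping, grid = object$grid),
            class = "condition_stats")
}

#' @export
print.condition_stats <- function(x, ...) {
  cat(sprintf("Condition statistics over '%s': %d conditions x %d units\n",
              x$grouping, length(x$conditions), nrow(x$mean)))
  cat("  conditions:", paste(sprintf("%s (n=%d)", x$conditions, x$n), collapse = ", "), "\n")
  invisible(x)
}

#' Condition preference map
#'
#' Assigns each map unit the condition eliciting its highest mean activation.
#' The preference strength is the margin of the winner over the runner-up
#' condition (for two conditions, the absolute difference of the two means).
#' Ties for the winner are resolved by condition order and flagged.
#'
#' @param stats a [condition_stats()] object.
#' @param conditions conditions to compare (default: all in `stats`); order
#'   sets the tie-break priority.
#' @return An object of class `"preference_map"`: list with W x H matrices
#'   `preferred` (condition labels), `strength`, `tie`, plus `conditions`,
#'   `mode` (`"two-way"` or `"n-way"`), `grid`.
#' @export
preference_map <- function(stats, conditions = NULL) {
  stopifnot(inherits(stats, "condition_stats"))
  if (is.null(conditions)) conditions <- stats$conditions
  if (length(conditions) < 2L) stopf("need at least 2 conditions")
  if (!all(conditions %in% stats$conditions))
    stopf("unknown condition(s): %s",
          paste(setdiff(conditions, stats$conditions), collapse = ", "))
  mu <- stats$mean[, conditions, drop = FALSE]
  win <- apply(mu, 1L, which.max)                 # first max = condition-order tie-break
  sorted <- apply(mu, 1L, function(m) sort(m, decreasing = TRUE)[1:2])
  strength <- sorted[1, ] - sorted[2, ]
  tie <- apply(mu, 1L, function(m) sum(m == max(m)) > 1L)
  structure(list(
    preferred = unit_to_grid(conditions[win], stats$grid),
    strength = unit_to_grid(strength, stats$grid),
    tie = unit_to_grid(tie, stats$grid),
    conditions = conditions,
    mode = if (length(conditions) == 2L) "two-way" else "n-way",
    grouping = stats$grouping,
    grid = stats$grid
  ), class = "preference_map")
}

#' @export
print.preference_map <- function(x, ...) {
  cat(sprintf("%s preference map (%d x %d) over '%s': %s\n",
              x$mode, x$grid[1], x$grid[2], x$grouping,
              paste(x$conditions, collapse = " vs ")))
  tab <- table(factor(grid_to_unit(x$preferred), levels = x$conditions))
  cat("  units preferring:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  if (any(x$tie)) cat("  ties at", sum(x$tie), "unit(s)\n")
  invisible(x)
}

#' @export
plot.preference_map <- function(x, ...) {
  code <- unit_to_grid(match(grid_to_unit(x$preferred), x$conditions), x$grid)
  cols <- grDevices::hcl.colors(length(x$conditions), "Dark 3")
  image_grid(code, main = paste("Preference:", paste(x$conditions, collapse = " / ")),
             zlim = c(1, length(x$conditions)), col = cols, ...)
  graphics::legend("topright", legend = x$conditions, fill = cols, bty = "n",
                   cex = 0.8, inset = c(-0.02, 0), xpd = TRUE)
  invisible(x)
}

# Internal: shared target/rest split for the selectivity metrics.
selectivity_split <- function(x, labels, target, grouping, exclude) {
  g <- aligned_labels(x, labels, grouping)
  if (!target %in% g) stopf("target condition '%s' not present in '%s'", target, grouping)
  keep <- !(g %in% exclude) | g == target
  is_target <- g == target
  if (sum(is_target) < 2L) stopf("target condition needs at least 2 images")
  if (sum(keep & !is_target) < 2L) stopf("non-target pool needs at least 2 images")
  list(g = g, keep = keep, is_target = is_target)
}

# Internal: build a selectivity_map object from unit scores.
new_selectivity_map <- function(score, undefined, metric, target, grouping, grid,
                                n_target, n_rest) {
  structure(list(score = unit_to_grid(score, grid),
                 undefined = unit_to_grid(undefined, grid),
                 metric = metric, target = target, grouping = grouping,
                 grid = grid, n_target = n_target, n_rest = n_rest),
            class = "selectivity_map")
}

#' Construct a selectivity map from per-unit scores
#'
#' Wraps an existing W x H score grid as a `"selectivity_map"`, e.g. scores
#' read back from disk or simulated for calibration studies. `NA` entries
#' are marked undefined.
#'
#' @param score W x H numeric matrix of per-unit scores.
#' @param metric `"dprime"` or `"si"` (or another short metric tag).
#' @param target label of the target condition the scores refer to.
#' @param grouping name of the attribute the target belongs to.
#' @return An object of class `"selectivity_map"`.
#' @export
as_selectivity_map <- function(score, metric = "dprime", target = "custom",
                               grouping = "category") {
  score <- as.matrix(score)
  new_selectivity_map(grid_to_unit(score), grid_to_unit(is.na(score)),
                      metric, target, grouping, dim(score),
                      NA_integer_, NA_integer_)
}

#' Construct a preference map from per-unit winners
#'
#' Wraps an existing W x H grid of preferred-condition labels (plus an
#' optional strength grid) as a `"preference_map"`.
#'
#' @param preferred W x H character matrix of winning condition labels.
#' @param conditions ordered condition labels (default: sorted unique values
#'   of `preferred`).
#' @param strength optional W x H numeric matrix of preference strengths
#'   (defaults to zeros).
#' @return An object of class `"preference_map"`.
#' @export
as_preference_map <- function(preferred, conditions = NULL, strength = NULL) {
  preferred <- as.matrix(preferred)
  if (is.null(conditions)) conditions <- sort(unique(as.vector(preferred)))
  if (!all(preferred %in% conditions)) stopf("preferred labels outside `conditions`")
  if (is.null(strength)) strength <- matrix(0, nrow(preferred), ncol(preferred))
  structure(list(preferred = preferred, strength = as.matrix(strength),
                 tie = matrix(FALSE, nrow(preferred), ncol(preferred)),
                 conditions = conditions,
                 mode = if (length(conditions) == 2L) "two-way" else "n-way",
                 grouping = "custom", grid = dim(preferred)),
            class = "preference_map")
}

#' d-prime category-selectivity map
#'
#' For each map unit, the standardized difference between its mean
#' activation to the target condition and to all remaining images:
#' `d' = (mean_target - mean_rest) / sqrt((var_target + var_rest) / 2)`,
#' with unbiased variances over per-image activations. Units with zero
#' pooled variance get an undefined (NA) score, flagged in `undefined`.
#'
#' @inheritParams condition_stats
#' @param target the target condition label.
#' @param exclude conditions removed from the non-target pool (e.g. dropping
#'   faces when asking how body-selective units behave without them).
#' @return An object of class `"selectivity_map"`: `score` and `undefined`
#'   W x H matrices plus metadata.
#' @export
dprime_map <- function(object, x, labels, target, grouping = "category",
                       exclude = NULL) {
  stopifnot(inherits(object, "som"))
  sp <- selectivity_split(x, labels, target, grouping, exclude)
  a <- som_activations(object, x)
  at <- a[sp$is_target, , drop = FALSE]
  ar <- a[sp$keep & !sp$is_target, , drop = FALSE]
  mt <- colMeans(at); mr <- colMeans(ar)
  vt <- apply(at, 2L, var); vr <- apply(ar, 2L, var)
  pooled <- (vt + vr) / 2
  undefined <- pooled == 0
  score <- ifelse(undefined, NA_real_, (mt - mr) / sqrt(pooled))
  new_selectivity_map(score, undefined, "dprime", target, grouping, object$grid,
                      nrow(at), nrow(ar))
}

#' Selectivity-index (SI) map
#'
#' Mean-normalized selectivity: `SI = (mean_target - mean_rest) /
#' (mean_target + mean_rest)` per unit, bounded in \[-1, 1\] when all mean
#' activations are nonnegative. Units whose two means sum to zero get an
#' undefined (NA) score.
#'
#' @inheritParams dprime_map
#' @return An object of class `"selectivity_map"`.
#' @export
si_map <- function(object, x, labels, target, grouping = "category",
                   exclude = NULL) {
  stopifnot(inherits(object, "som"))
  sp <- selectivity_split(x, labels, target, grouping, exclude)
  a <- som_activations(object, x)
  mt <- colMeans(a[sp$is_target, , drop = FALSE])
  mr <- colMeans(a[sp$keep & !sp$is_target, , drop = FALSE])
  undefined <- (mt + mr) == 0
  score <- ifelse(undefined, NA_real_, (mt - mr) / (mt + mr))
  new_selectivity_map(score, undefined, "si", target, grouping, object$grid,
                      sum(sp$is_target), sum(sp$keep & !sp$is_target))
}

#' @export
print.selectivity_map <- function(x, ...) {
  cat(sprintf("%s selectivity map (%d x %d), target '%s' (%d images) vs rest (%d)\n",
              if (x$metric == "dprime") "d-prime" else "SI",
              x$grid[1], x$grid[2], x$target, x$n_target, x$n_rest))
  cat(sprintf("  score range: [%.3f, %.3f]", min(x$score, na.rm = TRUE),
              max(x$score, na.rm = TRUE)))
  if (any(x$undefined)) cat(sprintf("; %d undefined unit(s)", sum(x$undefined)))
  cat("\n")
  invisible(x)
}

#' @export
plot.selectivity_map <- function(x, zlim = NULL, ...) {
  if (is.null(zlim)) {
    m <- max(abs(x$score), na.rm = TRUE)
    zlim <- c(-m, m)
  }
  image_grid(x$score, main = sprintf("%s selectivity: %s",
                                     if (x$metric == "dprime") "d'" else "SI", x$target),
             zlim = zlim, col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

#' Spatial nonuniformity of a selectivity map
#'
#' Softmax-normalizes the selectivity scores into a probability distribution
#' P over units and measures its divergence from the uniform distribution Q.
#' The default statistic is the square root of the symmetrized KL divergence,
#' `sqrt(KL(P||Q)/2 + KL(Q||P)/2)`; `type = "js"` gives the textbook
#' Jensen-Shannon distance (divergence against the mixture M = (P+Q)/2).
#' Both are 0 exactly when all scores are equal. Natural logarithms
#' throughout; softmax temperature 1.
#'
#' @param selectivity a [dprime_map()] / [si_map()] object (or a numeric
#'   vector/matrix of scores).
#' @param type `"symmetrized_kl"` (default) or `"js"`.
#' @return A nonnegative scalar.
#' @export
nonuniformity_score <- function(selectivity, type = c("symmetrized_kl", "js")) {
  type <- match.arg(type)
  s <- if (inherits(selectivity, "selectivity_map")) grid_to_unit(selectivity$score)
       else as.numeric(selectivity)
  if (anyNA(s)) stopf("selectivity map contains undefined scores")
  z <- s - max(s)
  p <- exp(z) / sum(exp(z))
  p <- pmax(p, .Machine$double.xmin)  # guard softmax underflow in the log terms
  q <- rep(1 / length(s), length(s))
  kl <- function(a, b) sum(a * log(a / b))
  if (type == "symmetrized_kl") {
    sqrt(kl(p, q) / 2 + kl(q, p) / 2)
  } else {
    m <- (p + q) / 2
    sqrt(kl(p, m) / 2 + kl(q, m) / 2)
  }
}

#' Most selective map unit
#'
#' @param selectivity a selectivity map.
#' @return 0-based grid coordinates `c(w, h)` of the unit with the maximum
#'   defined score; ties fall to the smallest row-major index.
#' @export
top_unit <- function(selectivity) {
  stopifnot(inherits(selectivity, "selectivity_map"))
  s <- grid_to_unit(selectivity$score)
  if (all(is.na(s))) stopf("all selectivity scores are undefined")
  k <- which.max(ifelse(is.na(s), -Inf, s))
  H <- unname(selectivity$grid[2])
  c(w = (k - 1L) %/% H, h = (k - 1L) %% H)
}
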