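# Spatial overlap between mesoscale selectivity and macroscale preference
# zones, plus representational-geometry summaries.

# Internal: AUC of the zone-fill sweep given the unit ordering (most
# selective first). zone_a/zone_b are logicals in row-major unit order.
# For each threshold k = ceil(pct/100 * n), pct = 1..100, computes the
# proportion of each zone's units captured in the top-k set; the curve
# (fill_b on x, fill_a on y), with (0,0) prepended, is integrated by the
# trapezoid rule. AUC > 0.5 means selective units concentrate in zone a.
fill_auc <- function(ord, zone_a, zone_b) {
  n <- length(ord)
  ks <- ceiling((1:100) / 100 * n)
  fa <- cumsum(zone_a[ord])[ks] / sum(zone_a)
  fb <- cumsum(zone_b[ord])[ks] / sum(zone_b)
  x <- c(0, fb); y <- c(0, fa)
  list(fill_a = fa, fill_b = fb,
       auc = sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

#' ROC overlap between a selectivity map and a preference map
#'
#' Sorts map units by selectivity (descending, ties by row-major index) and
#' sweeps a threshold from the top 1% to 100% of units. At each step it
#' records the proportion of all zone-a-preferring units and of all
#' zone-b-preferring units contained in the top set. Plotting the zone-a
#' fill against the zone-b fill traces an ROC-like curve from (0,0) to
#' (1,1); its trapezoidal area (with the origin prepended) is the AUC.
#' Chance is 0.5; values above 0.5 mean the most selective units concentrate
#' in zone a. The area between the curve and the diagonal is returned as
#' `auc_above_chance = auc - 0.5`.
#'
#' @param selectivity a [dprime_map()] / [si_map()] object with all scores
#'   defined.
#' @param preference a two-way [preference_map()] over `zone_a` and `zone_b`.
#' @param zone_a,zone_b the two preference-zone labels.
#' @return An object of class `"roc_overlap"`: list with `pct` (1..100),
#'   `fill_zone_a`, `fill_zone_b`, `auc`, `auc_above_chance`, labels and
#'   `n_units`.
#' @export
roc_overlap <- function(selectivity, preference, zone_a, zone_b) {
  stopifnot(inherits(selectivity, "selectivity_map"),
            inherits(preference, "preference_map"))
  if (preference$mode != "two-way" ||
      !setequal(preference$conditions, c(zone_a, zone_b)))
    stopf("preference map must be two-way over '%s' and '%s'", zone_a, zone_b)
  if (!identical(unname(selectivity$grid), unname(preference$grid)))
    stopf("selectivity and preference maps have different grids")
  s <- grid_to_unit(selectivity$score)
  if (anyNA(s)) stopf("selectivity map contains undefined scores")
  pref <- grid_to_unit(preference$preferred)
  za <- pref == zone_a; zb <- pref == zone_b
  if (!any(za)) stopf("no units prefer zone '%s'", zone_a)
  if (!any(zb)) stopf("no units prefer zone '%s'", zone_b)
  ord <- order(-s, seq_along(s))
  r <- fill_auc(ord, za, zb)
  structure(list(pct = 1:100, fill_zone_a = r$fill_a, fill_zone_b = r$fill_b,
                 auc = r$auc, auc_above_chance = r$auc - 0.5,
                 zone_a = zone_a, zone_b = zone_b,
                 metric = selectivity$metric, target = selectivity$target,
                 n_units = length(s)),
            class = "roc_overlap")
}

#' @export
print.roc_overlap <- function(x, ...) {
  cat(sprintf("ROC overlap: %s-selectivity for '%s' vs %s/%s preference zones (%d units)\n",
              x$metric, x$target, x$zone_a, x$zone_b, x$n_units))
  cat(sprintf("  AUC = %.3f (chance 0.5; area above diagonal %.3f)\n",
              x$auc, x$auc_above_chance))
  invisible(x)
}

#' @export
plot.roc_overlap <- function(x, ...) {
  graphics::plot(c(0, x$fill_zone_b), c(0, x$fill_zone_a), type = "l",
                 xlab = sprintf("proportion of %s-preferring units", x$zone_b),
                 ylab = sprintf("proportion of %s-preferring units", x$zone_a),
                 main = sprintf("Selectivity-preference overlap (AUC = %.3f)", x$auc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::lines(c(0, 1), c(0, 1), lty = 2)
  invisible(x)
}

#' Permutation test for selectivity-preference overlap
#'
#' Shuffles the selectivity scores across map units (the preference map
#' stays fixed), recomputing the ROC AUC each time, and reports the
#' proportion of null AUCs strictly greater than the observed one as the
#' p-value. `smoothed = TRUE` uses the add-one estimate
#' `(b + 1) / (n_perm + 1)` instead, which never returns exactly 0.
#'
#' @inheritParams roc_overlap
#' @param n_perm number of shuffles (default 1000).
#' @param seed integer seed for reproducibility.
#' @param smoothed use the add-one p-value estimate (default FALSE).
#' @return An object of class `"permutation_result"`: `observed_auc`,
#'   `null_aucs`, `p_value`, `n_perm`, `seed`, zone labels.
#' @export
permutation_test <- function(selectivity, preference, zone_a, zone_b,
                             n_perm = 1000, seed = NULL, smoothed = FALSE) {
  if (n_perm < 1L) stopf("n_perm must be at least 1")
  obs <- roc_overlap(selectivity, preference, zone_a, zone_b)
  s <- grid_to_unit(selectivity$score)
  pref <- grid_to_unit(preference$preferred)
  za <- pref == zone_a; zb <- pref == zone_b
  n <- length(s)
  null_aucs <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
    sp <- s[sample.int(n)]
    fill_auc(order(-sp, seq_len(n)), za, zb)$auc
  }, numeric(1)))
  b <- sum(null_aucs > obs$auc)
  p <- if (smoothed) (b + 1) / (n_perm + 1) else b / n_perm
  structure(list(observed_auc = obs$auc, null_aucs = null_aucs, p_value = p,
                 n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 smoothed = smoothed, zone_a = zone_a, zone_b = zone_b),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d shuffles): observed AUC = %.3f, p = %.4g\n",
              x$n_perm, x$observed_auc, x$p_value))
  cat(sprintf("  null AUC mean %.3f, 95%% of null in [%.3f, %.3f]\n",
              mean(x$null_aucs), stats::quantile(x$null_aucs, 0.025),
              stats::quantile(x$null_aucs, 0.975)))
  invisible(x)
}

#' Representational dissimilarity matrix
#'
#' Pairwise dissimilarity between samples, measured as 1 minus the Pearson
#' correlation of their feature vectors. Entries lie in \[0, 2\] with an
#' exactly-zero diagonal.
#'
#' @param x feature matrix (samples x features), each sample with nonzero
#'   variance across features; row names become matrix dimnames.
#' @return An n x n symmetric numeric matrix.
#' @export
rdm <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 samples")
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stopf("constant feature vector (undefined correlation) for sample(s): %s",
          paste(bad, collapse = ", "))
  }
  d <- 1 - cor(t(x))
  diag(d) <- 0
  d[d < 0] <- 0  # clip tiny negative round-off
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Multidimensional scaling embedding of a dissimilarity matrix
#'
#' Embeds samples in `out_dim` dimensions with classical (Torgerson)
#' multidimensional scaling via [stats::cmdscale()], and reports the
#' Kruskal stress-1 of the embedding against the input dissimilarities.
#' Classical scaling is deterministic; the `seed` argument is accepted for
#' interface stability with stochastic embedders.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (e.g. from
#'   [rdm()]).
#' @param out_dim output dimensionality (default 2).
#' @param seed unused by classical scaling; accepted for call compatibility.
#' @return A list with `points` (n x out_dim coordinates) and `stress`
#'   (Kruskal stress-1, 0 for perfectly Euclidean input).
#' @export
mds_embed <- function(d, out_dim = 2, seed = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stopf("dissimilarity matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stopf("dissimilarity matrix must have a zero diagonal")
  pts <- cmdscale(d, k = out_dim)
  if (ncol(pts) < out_dim)  # degenerate input (duplicates): pad flat dimensions
    pts <- cbind(pts, matrix(0, nrow(pts), out_dim - ncol(pts)))
  dd <- as.matrix(stats::dist(pts))
  lower <- lower.tri(d)
  denom <- sum(d[lower]^2)
  stress <- if (denom == 0) 0 else sqrt(sum((d[lower] - dd[lower])^2) / denom)
  rownames(pts) <- rownames(d)
  list(points = pts, stress = stress)
}

#' Moran's I spatial autocorrelation on a map grid
#'
#' Desk-scale measure of large-scale spatial clustering of a per-unit
#' quantity on the map (e.g. a binary preference label): Moran's I under
#' rook (4-neighbor) or queen (8-neighbor) adjacency with binary weights.
#'
#' @param grid numeric or logical W x H matrix of per-unit values.
#' @param adjacency `"rook"` (default) or `"queen"`.
#' @return Moran's I (about 0 under spatial randomness, toward 1 for
#'   large-scale clustering).
#' @export
morans_i <- function(grid, adjacency = c("rook", "queen")) {
  adjacency <- match.arg(adjacency)
  z <- as.numeric(grid) - mean(as.numeric(grid))
  dim(z) <- dim(grid)
  W <- nrow(z); H <- ncol(z)
  if (sum(z^2) == 0) return(0)
  shifts <- list(c(0, 1), c(1, 0))
  if (adjacency == "queen") shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  num <- 0; nw <- 0
  for (sft in shifts) {
    dw <- sft[1]; dh <- sft[2]
    rs <- seq_len(W - dw)
    cs <- if (dh >= 0) seq_len(H - dh) else seq(1 - dh, H)
    a <- z[rs, cs, drop = FALSE]
    b <- z[rs + dw, cs + dh, drop = FALSE]
    num <- num + 2 * sum(a * b)       # each undirected edge counted both ways
    nw <- nw + 2 * length(a)
  }
  (length(z) / nw) * (num / sum(z^2))
}
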