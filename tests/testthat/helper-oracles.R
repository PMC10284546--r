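# Independent brute-force oracles and toy-object builders.
# Every oracle is written as plain loops / closed forms, independent of the
# package's implementation paths.

# Minimal "som" object around a hand-built codebook (units row-major).
toy_som <- function(codebook, W, H) {
  structure(list(
    codebook = codebook,
    grid = c(W = W, H = H),
    coords = cbind(w = rep(0:(W - 1L), each = H), h = rep(0:(H - 1L), times = W)),
    trace = list(qe = numeric(0), qe_initial = NA_real_,
                 learning_rate = numeric(0), radius = numeric(0)),
    plane = NULL, config = list(), n_samples = 0L, data = NULL, call = NULL
  ), class = "som")
}

# Exhaustive BMU scan: per input row, loop all units, explicit distances.
oracle_bmu <- function(codebook, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    best <- 1L; best_d <- Inf
    for (k in seq_len(nrow(codebook))) {
      d <- sqrt(sum((x[i, ] - codebook[k, ])^2))
      if (d < best_d) { best_d <- d; best <- k }
    }
    out[i] <- best
  }
  out - 1L  # 0-based row-major
}

# Brute-force quantization error: mean over samples of min distance.
oracle_qe <- function(codebook, x) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    dmin <- Inf
    for (k in seq_len(nrow(codebook)))
      dmin <- min(dmin, sqrt(sum((x[i, ] - codebook[k, ])^2)))
    total <- total + dmin
  }
  total / nrow(x)
}

# Explicit per-unit dot products.
oracle_activations <- function(codebook, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  a <- matrix(0, nrow(x), nrow(codebook))
  for (i in seq_len(nrow(x)))
    for (k in seq_len(nrow(codebook)))
      a[i, k] <- sum(x[i, ] * codebook[k, ])
  a
}

# Group-by mean and unbiased variance per unit x condition.
oracle_condition_stats <- function(codebook, x, groups) {
  a <- oracle_activations(codebook, x)
  conds <- unique(groups)
  mu <- vv <- matrix(0, nrow(codebook), length(conds),
                     dimnames = list(NULL, conds))
  for (cc in conds) {
    sub <- a[groups == cc, , drop = FALSE]
    for (k in seq_len(ncol(a))) {
      m <- sum(sub[, k]) / nrow(sub)
      mu[k, cc] <- m
      vv[k, cc] <- sum((sub[, k] - m)^2) / (nrow(sub) - 1)
    }
  }
  list(mean = mu, var = vv)
}

# Direct evaluation of the selectivity formulas from raw activations.
oracle_dprime <- function(codebook, x, is_target, keep_rest = !is_target) {
  a <- oracle_activations(codebook, x)
  vapply(seq_len(nrow(codebook)), function(k) {
    at <- a[is_target, k]; ar <- a[keep_rest, k]
    mt <- mean(at); mr <- mean(ar)
    pooled <- (var(at) + var(ar)) / 2
    if (pooled == 0) NA_real_ else (mt - mr) / sqrt(pooled)
  }, numeric(1))
}

oracle_si <- function(codebook, x, is_target, keep_rest = !is_target) {
  a <- oracle_activations(codebook, x)
  vapply(seq_len(nrow(codebook)), function(k) {
    mt <- mean(a[is_target, k]); mr <- mean(a[keep_rest, k])
    if (mt + mr == 0) NA_real_ else (mt - mr) / (mt + mr)
  }, numeric(1))
}

# Pairwise 1 - Pearson correlation, explicit loop with the closed form.
oracle_rdm <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- x[i, ] - mean(x[i, ]); b <- x[j, ] - mean(x[j, ])
    d[i, j] <- 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  d
}

# Threshold-sweep AUC by explicit loops: sort by score (desc, index ties),
# walk pct = 1..100, accumulate trapezoids of fill_a over fill_b.
oracle_roc_auc <- function(score, zone_a, zone_b) {
  n <- length(score)
  ord <- order(-score, seq_len(n))
  xs <- 0; ys <- 0; auc <- 0
  for (pct in 1:100) {
    k <- ceiling(pct / 100 * n)
    top <- ord[seq_len(k)]
    fa <- sum(zone_a[top]) / sum(zone_a)
    fb <- sum(zone_b[top]) / sum(zone_b)
    auc <- auc + (fb - xs) * (fa + ys) / 2
    xs <- fb; ys <- fa
  }
  auc
}

# Moran's I by direct double loop over all unit pairs with binary weights.
oracle_morans_i <- function(grid, queen = FALSE) {
  W <- nrow(grid); H <- ncol(grid)
  z <- as.numeric(grid) - mean(as.numeric(grid))
  zg <- matrix(z, W, H)
  num <- 0; nw <- 0
  for (i1 in 1:W) for (j1 in 1:H) for (i2 in 1:W) for (j2 in 1:H) {
    di <- abs(i1 - i2); dj <- abs(j1 - j2)
    adj <- if (queen) (max(di, dj) == 1) else (di + dj == 1)
    if (adj) {
      num <- num + zg[i1, j1] * zg[i2, j2]
      nw <- nw + 1
    }
  }
  (W * H / nw) * num / sum(z^2)
}

# Top-2 eigenpairs from a dense eigendecomposition of the covariance matrix.
oracle_eigen2 <- function(x) {
  e <- eigen(cov(x), symmetric = TRUE)
  list(values = e$values[1:2], vectors = e$vectors[, 1:2, drop = FALSE])
}

# Row-major unfold of a W x H grid (duplicated here so tests do not rely on
# package internals).
grid_to_unit_test <- function(m) as.vector(t(m))

random_labels <- function(n, conds, seed) {
  withr::with_seed(seed, sample(conds, n, replace = TRUE))
}
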