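# Core map machinery: principal plane, grid shaping, schedules, BMU search,
# update rule, training loop, quantization error, similarity curve.

test_that("principal plane matches a dense eigendecomposition oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      x <- matrix(rnorm(50 * 10), 50, 10)
      p <- principal_plane(x)
      o <- oracle_eigen2(x)
      expect_equal(p$values, o$values, tolerance = 1e-10)
      # eigenvectors defined up to sign
      expect_equal(abs(colSums(p$vectors * o$vectors)), c(1, 1), tolerance = 1e-8)
      expect_equal(p$mean, colMeans(x))
      expect_lt(abs(sum(p$vectors[, 1] * p$vectors[, 2])), 1e-8)
    }
  })
})

test_that("principal plane handles axis-aligned and degenerate inputs", {
  withr::with_seed(2, {
    x <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 1e-4), rnorm(200, sd = 1e-4))
  })
  p <- principal_plane(x)
  expect_gt(abs(p$vectors[1, 1]), 0.9999)
  expect_equal(p$values[1], 4, tolerance = 0.5)
  expect_gte(p$values[1], p$values[2])
  expect_error(principal_plane(matrix(1, 10, 4)), "degenerate")
  expect_error(principal_plane(matrix(rnorm(4), 2, 2)), "at least 3")
})

test_that("grid shape follows the sqrt-eigenvalue aspect ratio", {
  expect_equal(unname(choose_grid_shape(400, c(1, 1))), c(20, 20))
  expect_equal(unname(choose_grid_shape(4, c(5, 5))), c(2, 2))
  # sqrt-eigval ratio 4: exhaustive factor-pair oracle, ratio error first,
  # then unit-count error, over pairs with both sides >= 2
  n <- 400; r <- 4
  cand <- expand.grid(W = 2:500, H = 2:250)
  cand <- cand[cand$W * cand$H <= 500 & cand$W * cand$H >= 300, ]
  err <- abs(log(cand$W / cand$H) - log(r))
  best <- cand[order(err, abs(cand$W * cand$H - n)), ][1, ]
  got <- choose_grid_shape(n, c(16, 1))  # sqrt(16/1) = 4
  expect_equal(unname(got), c(best$W, best$H))
  expect_equal(got[["W"]] * got[["H"]], 400)
  expect_equal(got[["W"]] / got[["H"]], 4)
})

test_that("learning rate and radius schedules have the stated closed forms", {
  expect_equal(som_learning_rate(0, 0.3, 100), 0.3)
  expect_equal(som_learning_rate(50, 0.3, 100), 0.15)
  expect_equal(som_learning_rate(99, 0.3, 100), 0.3 / 100)
  expect_error(som_learning_rate(100, 0.3, 100), "epoch index")
  expect_equal(som_radius(0, 10, 100), 10)
  expect_equal(som_radius(50, 10, 100), 5)
  expect_equal(som_radius(99, 10, 100), 0.1)
  expect_error(som_radius(100, 10, 100), "epoch index")
  # strictly decreasing, floored
  lr <- som_learning_rate(0:99, 0.3, 100)
  rad <- som_radius(0:99, 10, 100)
  expect_true(all(diff(lr) < 0))
  expect_true(all(diff(rad) < 0))
  expect_true(all(rad >= 1e-6))
  expect_equal(som_radius(999999, 10, 1e6, floor = 1e-2), 1e-2)
  # exponential variant decays from sigma0 toward 1
  rexp <- som_radius(0:29, 8, 30, schedule = "exponential")
  expect_equal(rexp[1], 8)
  expect_true(all(diff(rexp) < 0))
  expect_gt(rexp[30], 1)
})

test_that("grid distance and neighborhood weight follow the closed forms", {
  expect_equal(grid_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(grid_distance(c(0, 0), c(3, 4)), 5)
  withr::with_seed(3, {
    a <- matrix(sample(0:19, 40, replace = TRUE), 20, 2)
    b <- matrix(sample(0:19, 40, replace = TRUE), 20, 2)
  })
  expect_equal(grid_distance(a, b), grid_distance(b, a))
  expect_equal(neighborhood_weight(c(0, 0), c(0, 0), 5), 1)
  expect_equal(neighborhood_weight(c(0, 0), c(0, 10), 10), exp(-0.5))
  expect_error(neighborhood_weight(c(0, 0), c(0, 1), 0), "positive")
  # summed weights over a 20x20 grid match direct summation of the closed form
  co <- cbind(rep(0:19, each = 20), rep(0:19, times = 20))
  got <- sum(neighborhood_weight(c(7, 3), co, sigma = 4))
  direct <- 0
  for (i in 0:19) for (j in 0:19)
    direct <- direct + exp(-((7 - i)^2 + (3 - j)^2) / (2 * 4^2))
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("find_bmu matches the exhaustive scan oracle and breaks ties row-major", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      cb <- matrix(rnorm(36 * 8), 36, 8)
      fit <- toy_som(cb, 6, 6)
      x <- matrix(rnorm(100 * 8), 100, 8)
      expect_identical(find_bmu(fit, x)$unit, oracle_bmu(cb, x))
    }
  })
  # exact-match unit and tie toward the smaller row-major index
  cb <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 0))
  fit <- toy_som(cb, 2, 2)
  hit <- find_bmu(fit, c(1, 0))
  expect_equal(hit$unit, 0L)
  expect_equal(hit$distance, 0)
  tie <- find_bmu(fit, c(0.5, 0.5))  # units 0,1,2 equidistant
  expect_equal(tie$unit, 0L)
  expect_error(find_bmu(fit, c(1, 2, 3)), "dimension mismatch")
})

test_that("the update rule moves units toward the input without overshoot", {
  cb <- rbind(c(0, 0), c(2, 2), c(-1, 3), c(4, 0))
  x <- c(1, 1)
  # full step moves the BMU exactly onto the input
  up <- som_update(cb, x, bmu = c(0, 0), learning_rate = 1, sigma = 1e-9,
                   grid = c(2, 2))
  expect_equal(up[1, ], x)
  # eta = 1 at the BMU: 0.3 of the gap
  up2 <- som_update(cb, x, bmu = c(0, 0), learning_rate = 0.3, sigma = 2,
                    grid = c(2, 2))
  expect_equal(up2[1, ], c(0.3, 0.3))
  # distance to the input never increases, for any unit, over random cases
  withr::with_seed(31, {
    for (rep in 1:20) {
      cb <- matrix(rnorm(12 * 4), 12, 4)
      x <- rnorm(4)
      bmu_k <- oracle_bmu(cb, x) + 1L
      bmu_wh <- c((bmu_k - 1L) %/% 4L, (bmu_k - 1L) %% 4L)
      up <- som_update(cb, x, bmu_wh, learning_rate = runif(1, 0.05, 1),
                       sigma = runif(1, 0.3, 5), grid = c(3, 4))
      d_before <- sqrt(rowSums(sweep(cb, 2, x)^2))
      d_after <- sqrt(rowSums(sweep(up, 2, x)^2))
      expect_true(all(d_after <= d_before + 1e-12))
    }
  })
})

test_that("initialization places a lattice on the principal plane", {
  withr::with_seed(41, {
    z <- cbind(rnorm(300, sd = 3), rnorm(300, sd = 1))
    basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
    x <- z %*% t(basis) + 5
  })
  fit <- som(x, grid = c(8, 5), epochs = 1, learning_rate = 1e-12,
             init_sample_size = 300, radius = 1, seed = 1)
  p <- principal_plane(x)
  cb0 <- fit$codebook  # learning_rate ~ 0: codebook stays at initialization
  centered <- sweep(cb0, 2, p$mean)
  proj <- centered %*% p$vectors
  a <- proj[, 1] / sqrt(p$values[1])
  b <- proj[, 2] / sqrt(p$values[2])
  co <- fit$coords
  expect_equal(a, seq(-1, 1, length.out = 8)[co[, 1] + 1], tolerance = 1e-6)
  expect_equal(b, seq(-1, 1, length.out = 5)[co[, 2] + 1], tolerance = 1e-6)
  # corners at mean +/- sqrt(l1) v1 +/- sqrt(l2) v2; centroid at the mean
  off_plane <- centered - proj %*% t(p$vectors)
  expect_lt(max(abs(off_plane)), 1e-6)
  expect_equal(colMeans(cb0), p$mean, tolerance = 1e-6)
  expect_equal(max(abs(a)), 1, tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed and seed-sensitive", {
  x <- generate_planar_manifold(120, feature_dim = 6, seed = 7)
  f1 <- som(x, grid = c(4, 4), epochs = 4, init_sample_size = 50, seed = 99)
  f2 <- som(x, grid = c(4, 4), epochs = 4, init_sample_size = 50, seed = 99)
  expect_identical(f1$codebook, f2$codebook)
  expect_identical(f1$trace$qe, f2$trace$qe)
  f3 <- som(x, grid = c(4, 4), epochs = 4, init_sample_size = 50, seed = 100)
  expect_false(identical(f1$codebook, f3$codebook))
})

test_that("vanishing learning rate leaves the codebook at initialization", {
  x <- generate_planar_manifold(64, feature_dim = 5, seed = 8)
  f <- som(x, grid = c(4, 4), epochs = 1, learning_rate = 1e-15,
           init_sample_size = 64, seed = 1)
  g <- som(x, grid = c(4, 4), epochs = 1, learning_rate = 0.5,
           init_sample_size = 64, seed = 1)
  # same seed, same init; the tiny-step run must stay ~ at the shared init
  expect_gt(max(abs(f$codebook - g$codebook)), 1e-4)   # big step moved
  expect_equal(f$trace$qe[1], f$trace$qe_initial, tolerance = 1e-6)
})

test_that("training traces decay and quantization error matches its oracle", {
  x <- generate_planar_manifold(150, feature_dim = 8, seed = 9)
  f <- som(x, grid = c(5, 5), epochs = 6, init_sample_size = 100, seed = 5)
  expect_true(all(diff(f$trace$learning_rate) < 0))
  expect_true(all(diff(f$trace$radius) < 0))
  expect_length(f$trace$qe, 6)
  expect_equal(quantization_error(f), oracle_qe(f$codebook, x), tolerance = 1e-10)
  expect_equal(tail(f$trace$qe, 1), oracle_qe(f$codebook, x), tolerance = 1e-10)
  # hand cases
  cb <- rbind(c(0, 0))
  expect_equal(quantization_error(cb, rbind(c(3, 0), c(0, 5))), 4)
  expect_equal(quantization_error(cb, rbind(c(0, 0))), 0)
  withr::with_seed(10, {
    for (rep in 1:5) {
      cb <- matrix(rnorm(20 * 3), 20, 3)
      xx <- matrix(rnorm(30 * 3), 30, 3)
      expect_equal(quantization_error(cb, xx), oracle_qe(cb, xx), tolerance = 1e-10)
    }
  })
})

test_that("tuning similarity falls off with grid distance on a smooth codebook", {
  # tuning a linear function of grid position -> similarity decreasing in distance
  co <- cbind(rep(0:5, each = 6), rep(0:5, times = 6))
  cb <- cbind(co[, 1], co[, 2], co[, 1] + co[, 2], co[, 1] - co[, 2]) +
    withr::with_seed(207, matrix(rnorm(36 * 4, sd = 1e-6), 36, 4))
  fit <- toy_som(cb, 6, 6)
  s <- similarity_by_distance(fit)
  expect_true(all(s$distance > 0))
  expect_true(all(diff(s$similarity) < 0))
  # brute-force recomputation on a random codebook
  withr::with_seed(12, cbr <- matrix(rnorm(16 * 5), 16, 5))
  fitr <- toy_som(cbr, 4, 4)
  sr <- similarity_by_distance(fitr)
  pairs <- which(upper.tri(diag(16)), arr.ind = TRUE)
  cor_o <- apply(pairs, 1, function(p) cor(cbr[p[1], ], cbr[p[2], ]))
  cof <- fitr$coords
  d_o <- apply(pairs, 1, function(p) sqrt(sum((cof[p[1], ] - cof[p[2], ])^2)))
  for (i in seq_len(nrow(sr))) {
    sel <- round(d_o) == sr$distance[i]
    expect_equal(sr$similarity[i], mean(cor_o[sel]), tolerance = 1e-10)
    expect_equal(sr$n[i], sum(sel))
  }
  # constant tuning rows are excluded and counted
  cb2 <- cbr; cb2[1, ] <- 1
  s2 <- similarity_by_distance(toy_som(cb2, 4, 4))
  expect_equal(attr(s2, "n_excluded"), 15L)
})

test_that("topographic ordering emerges on a planar manifold", {
  x <- generate_planar_manifold(400, feature_dim = 16, seed = 13)
  f <- som(x, grid = c(7, 7), epochs = 12, init_sample_size = 200, seed = 14)
  dgrid <- as.matrix(stats::dist(f$coords))
  dtune <- as.matrix(stats::dist(f$codebook))
  lower <- lower.tri(dgrid)
  rho <- cor(dgrid[lower], dtune[lower], method = "spearman")
  expect_gt(rho, 0.5)
})
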