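# Patch sampling, whitening, ICA basis estimation, and colour directions.

test_that("patch sampling is interior, deterministic, and degenerate-safe", {
  img <- random_rgb_image(8, 8, seed = 1)
  ps <- sample_patches(img, n_per_image = 1, p = 8, seed = 2)
  expect_equal(ps$X[1, ], as.vector(img))   # only one possible placement

  imgs <- list(random_rgb_image(20, 30, 3), random_rgb_image(25, 25, 4))
  a <- sample_patches(imgs, 50, p = 8, seed = 9)
  b <- sample_patches(imgs, 50, p = 8, seed = 9)
  expect_identical(a$X, b$X)
  expect_true(all(a$source$row <= 25 - 8 + 1))

  uni <- array(0.4, c(16, 16, 3))
  pu <- sample_patches(uni, 100, p = 4, seed = 5)
  expect_equal(max(apply(pu$X, 2, var)), 0)

  expect_warning(sample_patches(list(random_rgb_image(4, 4, 1), imgs[[1]]),
                                10, p = 8, seed = 1), "skipped")
})

test_that("whitening yields identity covariance and stores a working inverse", {
  set.seed(21)
  X <- matrix(rnorm(2000 * 6), ncol = 6) %*% matrix(rnorm(36), 6, 6)
  wh <- whiten(X)
  expect_lt(max(abs(cov(wh$Z) - diag(wh$rank))), 1e-6)
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(wh$Z %*% wh$dewhitening - Xc)), 1e-8)

  # already-white data: transform stays orthogonal
  Zw <- matrix(rnorm(5000 * 4), ncol = 4)
  wh2 <- whiten(Zw)
  expect_lt(max(abs(cov(wh2$Z) - diag(4))), 1e-6)
})

test_that("rank-deficient and degenerate patch sets are handled", {
  set.seed(2)
  base <- matrix(rnorm(500 * 3), ncol = 3)
  X <- cbind(base, base[, 1] + base[, 2])     # rank 3 in 4 dims
  expect_warning(wh <- whiten(X), "rank")
  expect_identical(wh$rank, 3L)
  same <- matrix(1, 100, 5)
  expect_error(suppressWarnings(whiten(same)), "rank 0")
})

test_that("ICA recovers a planted 2-D mixing matrix", {
  errs <- replicate(5, NA_real_)
  for (s in 1:5) {
    set.seed(100 + s)
    S <- cbind(runif(3000, -1, 1), runif(3000, -1, 1))
    A <- matrix(c(1, 0.4, 0.6, 1), 2, 2)
    wh <- whiten(S %*% t(A))
    fit <- fit_ica(wh, seed = s)
    est <- apply(fit$A, 2, function(v) v / sqrt(sum(v^2)))
    tru <- apply(A, 2, function(v) v / sqrt(sum(v^2)))
    ang <- function(u, v) acos(pmin(1, abs(sum(u * v)))) * 180 / pi
    err <- max(apply(est, 2, function(u) min(ang(u, tru[, 1]), ang(u, tru[, 2]))))
    errs[s] <- err
  }
  expect_true(all(errs < 3))
})

test_that("mixing columns reconstruct the centred data (I = A s)", {
  ps <- generate_opponent_patches(800, p = 4, planted_angle = 60, seed = 31)
  wh <- whiten(ps, max_dim = 12)
  fit <- fit_ica(wh, seed = 7)
  recon <- fit$S %*% t(fit$A)
  target <- wh$Z %*% wh$dewhitening   # centred data within the retained subspace
  expect_lt(max(abs(recon - target)), 1e-8)
})

test_that("Gaussian-only data is reported as non-identifiable", {
  set.seed(3)
  X <- matrix(rnorm(4000), ncol = 2)
  wh <- whiten(X)
  expect_error(fit_ica(wh, seed = 1, maxit = 30), "converge")
})

test_that("bases are energy-ordered then unit-normalized with stable ties", {
  fake <- structure(list(
    A = cbind(c(3, 0), c(1, 0), c(0, 2)), S = matrix(0, 1, 3),
    energy = c(3, 1, 2), p = NA, mean = NULL, rank = NULL,
    direction = NULL, normalized = FALSE), class = "ica_basis_set")
  ord <- order_and_normalize(fake)
  expect_equal(ord$energy, c(3, 2, 1))
  expect_equal(colSums(ord$A^2), rep(1, 3), tolerance = 1e-12)
  expect_identical(ord$rank, 1:3)

  tie <- fake
  tie$A <- cbind(c(2, 0), c(0, 2), c(1, 0))
  tie$energy <- c(2, 2, 1)
  ot <- order_and_normalize(tie)
  expect_equal(ot$A[, 1], c(1, 0))   # equal energies keep original order
  expect_equal(ot$A[, 2], c(0, 1))
})

test_that("basis colour directions follow the opponent identities", {
  p <- 4
  grad <- seq(0, 1, length.out = p * p)
  # colour variation along pure red: angle 30
  red <- as.vector(outer(grad, c(1, 0, 0)))
  expect_equal(basis_color_direction(red, p), 30, tolerance = 1e-9)
  # achromatic axis: flagged
  grey <- as.vector(outer(grad, c(1, 1, 1)))
  expect_true(is.na(basis_color_direction(grey, p)))
  # blue vs yellow fold to the same axis at 90
  blue <- as.vector(outer(grad, c(0, 0, 1)))
  yellow <- as.vector(outer(grad, c(1, 1, 0)))
  expect_equal(basis_color_direction(blue, p), 90, tolerance = 1e-9)
  expect_equal(basis_color_direction(yellow, p), 90, tolerance = 1e-9)
  # sign flip of the basis leaves the axis angle unchanged
  set.seed(8)
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  basis <- as.vector(outer(grad, v))
  if (!is.na(basis_color_direction(basis, p))) {
    expect_equal(basis_color_direction(-basis, p), basis_color_direction(basis, p))
  }
  # flat basis: no colour variation at all
  expect_true(is.na(basis_color_direction(rep(0.2, 3 * p * p), p)))
})

test_that("direction histograms bin, fold, and conserve counts", {
  h <- direction_histogram(c(30, 30, 90), bin_width = 10)
  expect_equal(h$counts[h$bin_start == 30], 2L)
  expect_equal(h$counts[h$bin_start == 90], 1L)
  expect_equal(sum(h$counts), 3L)

  h2 <- direction_histogram(c(10, NA, 200, NA), bin_width = 10, folded = FALSE)
  expect_identical(h2$n_achromatic, 2L)
  expect_equal(sum(h2$counts), 2L)
  expect_equal(h2$counts[h2$bin_start == 200], 1L)

  # folded: 200 wraps to 20
  h3 <- direction_histogram(c(200), bin_width = 10, folded = TRUE)
  expect_equal(h3$counts[h3$bin_start == 20], 1L)
})

test_that("planted modes reappear in the direction histogram", {
  set.seed(17)
  # plant the modes at bin centres so each mode occupies one 10-degree bin
  angles <- c(rnorm(30, 35, 3), rnorm(30, 95, 3), rnorm(30, 135, 3)) %% 180
  h <- direction_histogram(angles, bin_width = 10)
  top3 <- h$bin_start[order(-h$counts)[1:3]]
  expect_setequal(top3, c(30, 90, 130))
})

test_that("the patch-to-histogram pipeline recovers a planted chromatic direction", {
  ps <- generate_opponent_patches(4000, p = 8, planted_angle = 130, seed = 99)
  wh <- whiten(ps, max_dim = 16)
  expect_lt(max(abs(cov(wh$Z) - diag(wh$rank))), 1e-6)
  fit <- order_and_normalize(basis_directions(fit_ica(wh, seed = 4)))
  h <- direction_histogram(fit$direction, bin_width = 10)
  mode_ctr <- h$bin_start[which.max(h$counts)] + 5
  expect_lte(min(abs(mode_ctr - 130), 180 - abs(mode_ctr - 130)), 10)
})

test_that("achromatic-only patch sets yield only flagged directions", {
  ps <- generate_opponent_patches(600, p = 4, planted_angle = 30,
                                  chromatic_fraction = 0, noise_sigma = 0,
                                  seed = 12)
  wh <- suppressWarnings(whiten(ps, max_dim = 6))
  fit <- basis_directions(fit_ica(wh, seed = 2))
  expect_true(all(is.na(fit$direction)))
})
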