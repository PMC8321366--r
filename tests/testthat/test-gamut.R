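# Gamut descriptors: discernible-colour counting, hull volume, ellipse fit.

test_that("discernible-colour count handles the degenerate and simple cases", {
  uni <- matrix(rep(c(50, 10, 10), 100), ncol = 3, byrow = TRUE)
  expect_equal(count_discernible_colors(uni, "lab-3d"), 1L)
  expect_equal(count_discernible_colors(uni, "ab-2d"), 1L)
  two <- rbind(uni, matrix(rep(c(80, -20, 30), 50), ncol = 3, byrow = TRUE))
  expect_equal(count_discernible_colors(two, "lab-3d"), 2L)
  expect_error(count_discernible_colors(matrix(numeric(0), 0, 3)), "empty")
})

test_that("discernible-colour count equals the brute-force set oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    px <- cbind(runif(500, 0, 100), runif(500, -30, 30), runif(500, -30, 30))
    expect_identical(count_discernible_colors(px, "lab-3d"), oracle_ndc(px, "lab-3d"))
    expect_identical(count_discernible_colors(px, "ab-2d"), oracle_ndc(px, "ab-2d"))
  }
})

test_that("counting is permutation/duplication invariant and 2-D <= 3-D", {
  set.seed(11)
  px <- cbind(runif(300, 0, 100), rnorm(300, 0, 15), rnorm(300, 0, 15))
  n3 <- count_discernible_colors(px)
  expect_identical(count_discernible_colors(px[sample(300), ]), n3)
  expect_identical(count_discernible_colors(rbind(px, px)), n3)
  expect_lte(count_discernible_colors(px, "ab-2d"), n3)
})

test_that("hull volume reproduces exactly known polytopes", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10))) +
    matrix(rep(c(30, -5, 5), each = 8), ncol = 3)
  expect_equal(convex_hull_volume(cube)$volume, 1000)
  for (seed in 1:6) {
    kc <- known_volume_cloud(150, seed)
    got <- convex_hull_volume(kc$pts)
    expect_false(got$degenerate)
    expect_equal(got$volume, kc$volume, tolerance = 1e-9)
  }
})

test_that("degenerate clouds are flagged with volume 0", {
  uni <- matrix(rep(c(50, 0, 0), 10), ncol = 3, byrow = TRUE)
  expect_true(gamut_volume(uni)$degenerate)
  expect_equal(gamut_volume(uni)$volume, 0)
  set.seed(2)
  flat <- cbind(runif(50, 0, 100), runif(50, -40, 40), 7)  # coplanar
  expect_true(convex_hull_volume(flat)$degenerate)
})

test_that("hull volume is monotone under adding points", {
  set.seed(5)
  pts <- matrix(rnorm(300, sd = 10), ncol = 3)
  v1 <- convex_hull_volume(pts[1:50, ])$volume
  v2 <- convex_hull_volume(pts)$volume
  expect_gte(v2, v1)
})

test_that("noise-free sampled ellipses are recovered to high precision", {
  pts <- ellipse_points(200, cx = 5, cy = -3, ra = 20, rb = 10, angle_deg = 30)
  fit <- fit_gamut_ellipse(pts)
  expect_equal(unname(fit$center), c(5, -3), tolerance = 1e-6)
  expect_equal(fit$semi_major, 20, tolerance = 1e-6)
  expect_equal(fit$semi_minor, 10, tolerance = 1e-6)
  expect_equal(fit$angle, 30, tolerance = 1e-4)
  expect_equal(fit$area, pi * fit$semi_major * fit$semi_minor)
})

test_that("a circle fits with axis ratio 1", {
  pts <- ellipse_points(100, 0, 0, 15, 15, 0)
  fit <- fit_gamut_ellipse(pts)
  expect_equal(fit$axis_ratio, 1, tolerance = 1e-6)
})

test_that("noisy ellipses are recovered within 2 percent", {
  for (seed in 1:20) {
    pts <- ellipse_points(1000, 5, -3, 20, 10, 30, noise = 0.5, seed = seed)
    fit <- fit_gamut_ellipse(pts)
    expect_equal(fit$semi_major, 20, tolerance = 0.02)
    expect_equal(fit$semi_minor, 10, tolerance = 0.02)
    expect_lt(abs(fit$angle - 30), 1)
  }
})

test_that("ellipse area/ratio are rotation invariant; angle shifts mod 180", {
  pts <- ellipse_points(400, 0, 0, 25, 12, 40, noise = 0.3, seed = 9)
  rot <- 73 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  f1 <- fit_gamut_ellipse(pts)
  f2 <- fit_gamut_ellipse(pts %*% t(R))
  expect_equal(f2$area, f1$area, tolerance = 1e-6)
  expect_equal(f2$axis_ratio, f1$axis_ratio, tolerance = 1e-6)
  expect_equal((f2$angle - f1$angle) %% 180, 73, tolerance = 1e-3)
})

test_that("ellipse fit rejects insufficient input", {
  expect_error(fit_gamut_ellipse(matrix(rnorm(8), 4, 2)), "at least 5")
  same <- matrix(rep(c(1, 2), 10), ncol = 2, byrow = TRUE)
  expect_error(fit_gamut_ellipse(same), "5 distinct|zero variance")
})

test_that("gamut summary composes its parts and is permutation invariant", {
  pt <- generate_painting(K = 9, noise_sigma = 1, shading_amplitude = 0, seed = 31)
  px <- matrix(pt$lab, ncol = 3)
  gs <- summarize_gamut(px)
  expect_identical(gs$n_discernible, count_discernible_colors(px))
  expect_equal(gs$volume, gamut_volume(px)$volume)
  ell <- fit_gamut_ellipse(px)
  expect_equal(gs$ellipse$area, ell$area)
  expect_equal(gs$mean_L, mean(px[, 1]))
  gs2 <- summarize_gamut(px[sample(nrow(px)), ])
  expect_equal(as.data.frame(gs2), as.data.frame(gs))
})

test_that("uniform images yield a degenerate summary", {
  uni <- matrix(rep(c(50, 10, -5), 64), ncol = 3, byrow = TRUE)
  gs <- summarize_gamut(uni)
  expect_identical(gs$n_discernible, 1L)
  expect_equal(gs$volume, 0)
  expect_true(gs$volume_degenerate)
  expect_null(gs$ellipse)
  expect_match(gs$ellipse_error, "distinct|variance")
})
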