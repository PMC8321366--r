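# Relevant-colour routes: click aggregation, computational extraction,
# subjective palettes, hue/chroma tables, palette overlap.

lab_uniform_image <- function(h, w, color) {
  array(rep(color, each = h * w), c(h, w, 3))
}

test_that("click aggregation averages the 5x5 window", {
  img <- lab_uniform_image(20, 20, c(50, 10, -5))
  sel <- aggregate_click(img, 10, 10)
  expect_equal(sel$color, c(50, 10, -5))

  # checkerboard window: 13 of c1, 12 of c2
  c1 <- c(40, 20, 0); c2 <- c(60, -10, 30)
  img2 <- lab_uniform_image(9, 9, c(0, 0, 0))
  for (i in 1:9) for (j in 1:9) {
    img2[i, j, ] <- if ((i + j) %% 2 == 0) c1 else c2
  }
  sel2 <- aggregate_click(img2, 5, 5)
  expect_equal(sel2$color, (13 * c1 + 12 * c2) / 25)
})

test_that("clicks whose window crosses the border are rejected", {
  img <- lab_uniform_image(20, 20, c(50, 0, 0))
  expect_error(aggregate_click(img, 1, 1), "border")
  expect_error(aggregate_click(img, 2, 10), "border")
  expect_error(aggregate_click(img, 10, 19), "border")
  expect_silent(aggregate_click(img, 3, 3))
})

test_that("extraction recovers a well-separated mosaic palette exactly", {
  pt <- generate_painting(K = 21, noise_sigma = 0, shading_amplitude = 0, seed = 51)
  pal <- extract_relevant_colors(pt$lab)
  expect_s3_class(pal, "relevant_palette")
  expect_identical(pal$size, 21L)
  d <- delta_e_cross(pt$truth_palette$colors, pal$colors)
  expect_lt(max(apply(d, 1, min)), 1)
})

test_that("a uniform admissible image yields a single-colour palette", {
  img <- lab_uniform_image(16, 16, c(50, 20, 10))
  pal <- extract_relevant_colors(img)
  expect_identical(pal$size, 1L)
  expect_equal(unname(pal$colors[1, ]), c(50, 20, 10), tolerance = 1e-9)
})

test_that("the chroma gate removes low-chroma generator colours", {
  pt <- generate_painting(K = 6, noise_sigma = 0, shading_amplitude = 0, seed = 8)
  truth <- pt$truth_palette$colors
  # replace one colour region with a near-neutral colour below the gate
  neutral <- c(truth[1, 1], 1.5, 0)   # chroma 1.5 < 5
  lab <- pt$lab
  mask <- pt$color_map == 1
  for (k in 1:3) {
    ch <- lab[, , k]; ch[mask] <- neutral[k]; lab[, , k] <- ch
  }
  pal <- extract_relevant_colors(lab)
  expect_identical(pal$size, 5L)
  expect_gt(min(delta_e_cross(matrix(neutral, 1), pal$colors)), 5)
})

test_that("the lightness gate removes out-of-range colours", {
  img <- lab_uniform_image(16, 16, c(98, 20, 10))  # L above the default gate
  expect_error(extract_relevant_colors(img), "no relevant colours")
  cfg <- palette_config(L_range = c(5, 99))
  expect_identical(extract_relevant_colors(img, cfg)$size, 1L)
})

test_that("extracted palettes satisfy their separation constraint", {
  for (seed in c(3, 14)) {
    pt <- generate_painting(K = 13, noise_sigma = 2, shading_amplitude = 3,
                            seed = seed)
    pal <- extract_relevant_colors(pt$lab)
    d <- delta_e_cross(pal$colors)
    expect_gte(min(d[upper.tri(d)]), 15)
  }
})

test_that("palette size is monotone under tightening and extraction is deterministic", {
  pt <- generate_painting(K = 13, noise_sigma = 2, shading_amplitude = 3, seed = 23)
  sizes_de <- vapply(c(15, 25, 40), function(de) {
    extract_relevant_colors(pt$lab, palette_config(delta_e_min = de))$size
  }, integer(1))
  expect_true(all(diff(sizes_de) <= 0))
  sizes_ch <- vapply(c(5, 20, 35), function(ch) {
    extract_relevant_colors(pt$lab, palette_config(chroma_min = ch))$size
  }, integer(1))
  expect_true(all(diff(sizes_ch) <= 0))
  expect_identical(extract_relevant_colors(pt$lab), extract_relevant_colors(pt$lab))
})

test_that("subjective palettes keep each selection unless merging is requested", {
  set.seed(4)
  sel <- data.frame(L = runif(15, 20, 80), a = rnorm(15, 0, 30),
                    b = rnorm(15, 0, 30))
  pal <- subjective_palette(sel)
  expect_identical(pal$size, 15L)      # one palette entry per selection
  expect_identical(pal$provenance, "subjective")

  dup <- sel[c(1, 1), ]
  expect_identical(subjective_palette(dup, merge_delta_e = 5)$size, 1L)
})

test_that("single-linkage merging chains colours at sub-threshold spacing", {
  chain <- data.frame(L = c(50, 54, 58), a = 0, b = 0)  # spacing 4 < 5
  merged <- subjective_palette(chain, merge_delta_e = 5)
  expect_identical(merged$size, 1L)
  expect_equal(unname(merged$colors[1, ]), c(54, 0, 0))
  apart <- data.frame(L = c(50, 54, 70), a = 0, b = 0)
  expect_identical(subjective_palette(apart, merge_delta_e = 5)$size, 2L)
  expect_error(subjective_palette(list()), "at least one")
})

test_that("hue/chroma tables decompose and conserve counts", {
  pal <- new_palette(rbind(c(50, 0, 10)), "subjective")
  hc <- hue_chroma_table(pal)
  expect_equal(hc$table$hue, 90)
  expect_equal(hc$table$chroma, 10)

  set.seed(6)
  pal2 <- new_palette(cbind(runif(40, 20, 80), rnorm(40, 0, 25),
                            rnorm(40, 0, 25)), "subjective")
  hc2 <- hue_chroma_table(pal2)
  expect_equal(sum(hc2$hue_hist$count), 40)
  expect_equal(sum(hc2$chroma_hist$count), 40)
})

test_that("low-chroma fraction is computed correctly on a constructed palette", {
  chroma <- c(5, 10, 15, 20, 25, 30, 34, 40, 50, 60)   # 7 of 10 below 35
  pal <- new_palette(cbind(50, chroma, 0), "subjective")
  hc <- hue_chroma_table(pal)
  expect_equal(mean(hc$table$chroma < 35), 0.7)
})

test_that("palette overlap reports identity, disjointness, and partial matches", {
  set.seed(10)
  pal <- new_palette(cbind(runif(8, 20, 80), rnorm(8, 0, 30), rnorm(8, 0, 30)),
                     "computational")
  ov <- palette_overlap(pal, new_palette(pal$colors, "subjective"), tol = 10)
  expect_equal(ov$subjective_covered, 1)
  expect_equal(ov$computational_covered, 1)
  expect_equal(ov$hull_area_iou, 1, tolerance = 1e-9)

  far <- new_palette(sweep(pal$colors, 2, c(0, 300, 0), "+"), "subjective")
  ov2 <- palette_overlap(pal, far, tol = 10)
  expect_equal(ov2$subjective_covered, 0)
  expect_equal(ov2$hull_area_iou, 0)

  # constructed 4 vs 4 with exactly 2 matches at tol 10
  comp <- new_palette(rbind(c(50, 0, 0), c(50, 40, 0), c(50, 0, 40),
                            c(50, -40, 0)), "computational")
  subj <- new_palette(rbind(c(50, 5, 0), c(50, 44, 3), c(70, 0, -60),
                            c(20, 60, 60)), "subjective")
  ov3 <- palette_overlap(comp, subj, tol = 10)
  expect_equal(ov3$subjective_covered, 0.5)
})

test_that("degenerate hulls disable the area measure but not nearest-colour", {
  comp <- new_palette(rbind(c(50, 0, 0), c(60, 0, 0)), "computational")
  subj <- new_palette(rbind(c(50, 1, 0)), "subjective")
  ov <- palette_overlap(comp, subj, tol = 5)
  expect_true(is.na(ov$hull_area_iou))
  expect_equal(ov$subjective_covered, 1)
})
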