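# Synthetic data generators: palette-structured paintings (Voronoi colour
# regions with CIELAB noise and smooth lightness shading), a simulated
# observer clicking inside relevant chromatic areas, and planted
# colour-opponent patch sets for the ICA direction analysis.

#' Sample a well-separated CIELAB palette inside the sRGB gamut
#'
#' Rejection sampling: colours are proposed uniformly in lightness, hue, and
#' chroma within the given ranges, kept when they fall inside the sRGB gamut
#' and lie at least `delta_e_sep` Delta E*ab from every accepted colour.
#' Restarts from scratch when it stalls; errors when (K, delta_e_sep) are
#' infeasible within the attempt budget.
#'
#' @param K Number of colours.
#' @param delta_e_sep Minimum pairwise separation in Delta E*ab.
#' @param L_range,chroma_range Proposal ranges for lightness and chroma. The
#'   defaults keep colours clear of the extraction gates (lightness 5-95,
#'   chroma >= 5) so a generated palette is recoverable by construction.
#' @param rgb_margin Margin from the sRGB channel bounds: accepted colours
#'   have all channels in `[rgb_margin, 1 - rgb_margin]`, leaving headroom so
#'   per-pixel noise does not clip a large share of a colour's pixels.
#' @param max_restarts,max_tries Attempt budget.
#' @return K x 3 CIELAB matrix.
#' @export
sample_lab_palette <- function(K, delta_e_sep = 30, L_range = c(25, 80),
                               chroma_range = c(10, 70), rgb_margin = 0.08,
                               max_restarts = 60, max_tries = 4000) {
  stopifnot(K >= 1, delta_e_sep > 0, rgb_margin >= 0, rgb_margin < 0.5)
  for (restart in seq_len(max_restarts)) {
    acc <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(acc) < K && tries < max_tries) {
      tries <- tries + 1L
      L <- stats::runif(1, L_range[1], L_range[2])
      ch <- stats::runif(1, chroma_range[1], chroma_range[2])
      hu <- stats::runif(1, 0, 2 * pi)
      cand <- c(L, ch * cos(hu), ch * sin(hu))
      rgb <- lab_to_srgb(cand)
      if (min(rgb) < rgb_margin || max(rgb) > 1 - rgb_margin) next
      if (nrow(acc) && min(delta_e_cross(matrix(cand, 1), acc)) < delta_e_sep) next
      acc <- rbind(acc, cand)
    }
    if (nrow(acc) == K) {
      dimnames(acc) <- list(NULL, c("L", "a", "b"))
      return(acc)
    }
  }
  stop("could not place ", K, " colours at separation ", delta_e_sep,
       " inside the sRGB gamut; relax K or delta_e_sep")
}

# box-sum of a logical matrix over centred 5x5 windows, via summed-area table;
# TRUE where the whole window lies inside the mask (and inside the image)
.window25_inside <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  sat <- apply(apply(mask, 2, cumsum), 1, cumsum)  # w x h transposed
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  res <- matrix(FALSE, h, w)
  if (h >= 5 && w >= 5) {
    ys <- 3:(h - 2); xs <- 3:(w - 2)
    s <- sat[ys + 3, xs + 3, drop = FALSE] - sat[ys - 2, xs + 3, drop = FALSE] -
      sat[ys + 3, xs - 2, drop = FALSE] + sat[ys - 2, xs - 2, drop = FALSE]
    res[ys, xs] <- s == 25
  }
  res
}

#' Generate a synthetic palette-structured painting
#'
#' Emulates the structure the relevant-colour analysis assumes: a discrete
#' palette of K well-separated CIELAB colours laid out as Voronoi regions over
#' random sites (every colour used at least once), per-pixel Gaussian CIELAB
#' noise, and optional low-frequency lightness shading. The result is clipped
#' into the sRGB gamut; the clipped-pixel fraction is recorded because heavy
#' clipping would distort the truth palette. Deterministic per seed.
#'
#' Site layouts are resampled (bounded attempts) until every colour holds at
#' least `min_pixels` pixels and contains a fully interior 5 x 5 window, so
#' both the extraction recovery properties and the simulated observer are
#' exercisable by construction.
#'
#' @param K Number of palette colours (default 21, the typical size of a
#'   subjective painting palette).
#' @param width,height Canvas size in pixels.
#' @param delta_e_sep Minimum pairwise palette separation (default 30).
#' @param noise_sigma Per-channel CIELAB noise standard deviation (default 3).
#' @param shading_amplitude Peak amplitude of the smooth L* shading field
#'   (default 5).
#' @param n_regions Number of Voronoi sites (default `3 * K`).
#' @param min_pixels Minimum pixels per colour (default 64).
#' @param seed Integer seed (mandatory).
#' @return List of class `synthetic_painting`: `image` (h x w x 3 sRGB
#'   array), `lab` (h x w x 3 CIELAB array, post noise/shading/clipping),
#'   `truth_palette` (`relevant_palette`), `color_map` (h x w matrix of
#'   generator colour indices), `region_map` (h x w matrix of site indices),
#'   `clip_fraction`, `params`.
#' @export
generate_painting <- function(K = 21, width = 128, height = 128,
                              delta_e_sep = 30, noise_sigma = 3,
                              shading_amplitude = 5, n_regions = 3 * K,
                              min_pixels = 64, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(K >= 1, n_regions >= K)
  set.seed(seed)
  truth <- sample_lab_palette(K, delta_e_sep)

  # site layout: retry until every colour has enough area and an interior
  # 5x5 window
  xg <- matrix(rep(seq_len(width), each = height), height, width)
  yg <- matrix(rep(seq_len(height), width), height, width)
  color_map <- NULL
  for (attempt in 1:50) {
    sx <- stats::runif(n_regions, 1, width)
    sy <- stats::runif(n_regions, 1, height)
    site_color <- c(seq_len(K),
                    if (n_regions > K) sample.int(K, n_regions - K, replace = TRUE))
    site_color <- sample(site_color)  # shuffle so colour 1 isn't always first
    d2 <- outer(as.vector(yg), sy, function(a, b) (a - b)^2) +
      outer(as.vector(xg), sx, function(a, b) (a - b)^2)
    region <- max.col(-d2, ties.method = "first")
    cm <- matrix(site_color[region], height, width)
    ok <- TRUE
    for (k in seq_len(K)) {
      mask <- cm == k
      if (sum(mask) < min_pixels || !any(.window25_inside(mask))) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      color_map <- cm
      region_map <- matrix(region, height, width)
      break
    }
  }
  if (is.null(color_map)) {
    stop("could not lay out ", K, " colours with >= ", min_pixels,
         " pixels each on a ", width, "x", height, " canvas")
  }

  lab <- array(truth[as.vector(color_map), ], dim = c(height, width, 3))
  if (shading_amplitude > 0) {
    fx <- stats::runif(1, 0.5, 1.5) / width
    fy <- stats::runif(1, 0.5, 1.5) / height
    ph <- stats::runif(2, 0, 2 * pi)
    field <- sin(2 * pi * fx * xg + ph[1]) * sin(2 * pi * fy * yg + ph[2])
    lab[, , 1] <- lab[, , 1] + shading_amplitude * field
  }
  if (noise_sigma > 0) {
    lab <- lab + array(stats::rnorm(length(lab), 0, noise_sigma), dim = dim(lab))
  }
  rgb <- lab_to_srgb(lab)
  clip_fraction <- mean(apply(rgb < 0 | rgb > 1, c(1, 2), any))
  rgb <- pmin(pmax(rgb, 0), 1)
  lab_clipped <- srgb_to_lab(rgb)

  structure(list(
    image = rgb, lab = lab_clipped,
    truth_palette = new_palette(truth, "computational"),
    color_map = color_map, region_map = region_map,
    clip_fraction = clip_fraction,
    params = list(K = K, width = width, height = height,
                  delta_e_sep = delta_e_sep, noise_sigma = noise_sigma,
                  shading_amplitude = shading_amplitude,
                  n_regions = n_regions, seed = seed)),
    class = "synthetic_painting")
}

#' @export
print.synthetic_painting <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("synthetic painting %dx%d: K = %d, separation %.0f dE,",
                     " noise %.1f, shading %.1f, clipped %.1f%%\n"),
              p$width, p$height, p$K, p$delta_e_sep, p$noise_sigma,
              p$shading_amplitude, 100 * x$clip_fraction))
  invisible(x)
}

#' Simulate an observer clicking relevant colours
#'
#' For each generator colour the observer clicks, with probability
#' `click_prob` weighted by a chroma bias, on a uniformly random pixel whose
#' whole 5 x 5 averaging window lies inside a region of that colour (so the
#' averaged selection is uncontaminated by neighbouring regions). The chroma
#' bias raises the probability of clicking high-chroma colours:
#' `p_k = click_prob * (chroma_k / max chroma)^chroma_bias`, emulating the
#' scarcity of low-chroma selections in human data. Colours without a large
#' enough region are skipped with a warning. Deterministic per seed.
#'
#' @param painting A [generate_painting()] result.
#' @param click_prob Baseline per-colour click probability (default 1).
#' @param chroma_bias Chroma bias exponent (default 0 = unbiased).
#' @param seed Integer seed (mandatory).
#' @return Data frame with one row per click: `x`, `y`, `L`, `a`, `b` (the
#'   averaged selection colour) and `truth_index`.
#' @export
simulate_observer <- function(painting, click_prob = 1, chroma_bias = 0,
                              seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(painting, "synthetic_painting"))
  set.seed(seed)
  truth <- painting$truth_palette$colors
  chroma <- lab_to_polar(truth)[, "chroma"]
  wgt <- if (chroma_bias == 0) rep(1, nrow(truth)) else {
    (chroma / max(chroma, .Machine$double.eps))^chroma_bias
  }
  rows <- list()
  for (k in seq_len(nrow(truth))) {
    if (stats::runif(1) > click_prob * wgt[k]) next
    inside <- .window25_inside(painting$color_map == k)
    cand <- which(inside)
    if (!length(cand)) {
      warning("colour ", k, " has no interior 5x5 window; skipped")
      next
    }
    pick <- cand[sample.int(length(cand), 1)]
    y <- (pick - 1L) %% nrow(inside) + 1L
    x <- (pick - 1L) %/% nrow(inside) + 1L
    sel <- aggregate_click(painting$lab, x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      x = x, y = y, L = sel$color[1], a = sel$color[2], b = sel$color[3],
      truth_index = k)
  }
  if (!length(rows)) {
    return(data.frame(x = integer(0), y = integer(0), L = numeric(0),
                      a = numeric(0), b = numeric(0), truth_index = integer(0)))
  }
  do.call(rbind, rows)
}

# RGB axis whose opponent-plane projection sits exactly at `angle_deg`:
# the opponent transform rows are orthonormal, so the transpose is a right
# inverse
.opponent_axis <- function(angle_deg) {
  th <- angle_deg * pi / 180
  tmat <- rbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  as.vector(t(tmat) %*% c(cos(th), sin(th)))
}

#' Generate patches with a planted chromatic-opponent direction
#'
#' Test harness for the ICA colour-direction pipeline: a fraction of the
#' patches vary along a single 3-D colour axis whose (RG, BY) projection sits
#' exactly at `planted_angle`, modulated by oriented sinusoidal gratings of
#' random orientation, frequency, and phase; the rest are achromatic-gradient
#' distractors (variation along the grey axis). Gaussian pixel noise is added
#' on top. Labels are retained. Deterministic per seed.
#'
#' @param n Total number of patches (must exceed 3p^2 for later whitening).
#' @param p Patch edge length (default 8).
#' @param planted_angle Planted opponent-plane angle in degrees.
#' @param noise_sigma Per-pixel Gaussian noise sd (default 0.02).
#' @param chromatic_fraction Fraction of chromatic patches (default 0.8).
#' @param seed Integer seed (mandatory).
#' @return A `patch_set` with an extra `chromatic` logical vector.
#' @export
generate_opponent_patches <- function(n, p = 8, planted_angle,
                                      noise_sigma = 0.02,
                                      chromatic_fraction = 0.8, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n > 3 * p * p)
  set.seed(seed)
  axis_c <- .opponent_axis(planted_angle)
  axis_a <- c(1, 1, 1) / sqrt(3)
  chrom <- stats::runif(n) < chromatic_fraction
  xs <- matrix(rep(seq_len(p), each = p), p, p)
  ys <- matrix(rep(seq_len(p), p), p, p)
  X <- matrix(0, n, 3 * p * p)
  for (i in seq_len(n)) {
    ori <- stats::runif(1, 0, pi)
    freq <- stats::runif(1, 1, 3) / p
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.08, 0.25)
    g <- amp * sin(2 * pi * freq * (xs * cos(ori) + ys * sin(ori)) + ph)
    ax <- if (chrom[i]) axis_c else axis_a
    patch <- 0.5 + outer(as.vector(g), ax)      # p^2 x 3
    X[i, ] <- as.vector(patch)
  }
  if (noise_sigma > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sigma), nrow = n)
  }
  structure(list(X = X, p = p, source = NULL, seed = seed, chromatic = chrom),
            class = "patch_set")
}
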