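# PHOG-style image complexity descriptors: a spatial pyramid of oriented
# gradient histograms and the four derived metrics (self-similarity,
# complexity, anisotropy, Birkhoff-like ratio).
#
# Conventions (config-exposed where reasonable): 3x3 Sobel gradients scaled so
# a ramp of slope s yields gradient s, replicate padding at borders, per-pixel
# channel = the RGB channel with the largest gradient magnitude, orientations
# folded to [0, 180), magnitude-weighted histograms, L1 normalization,
# median aggregation for self-similarity. Intensities are on the 0-255 scale.

# gradient field of an RGB image: per-pixel gx, gy, magnitude of the
# maximum-magnitude channel (0-255 intensity scale)
.gradient_field <- function(img) {
  img <- as_rgb_image(img) * 255
  h <- dim(img)[1]; w <- dim(img)[2]
  ry <- c(1, seq_len(h), h)  # replicate padding
  rx <- c(1, seq_len(w), w)
  best_mag <- matrix(-1, h, w)
  gx <- gy <- matrix(0, h, w)
  for (k in 1:3) {
    p <- img[ry, rx, k]
    ctr_y <- 2:(h + 1); ctr_x <- 2:(w + 1)
    up <- ctr_y - 1L; dn <- ctr_y + 1L
    lf <- ctr_x - 1L; rt <- ctr_x + 1L
    kx <- (p[up, rt] + 2 * p[ctr_y, rt] + p[dn, rt] -
           p[up, lf] - 2 * p[ctr_y, lf] - p[dn, lf]) / 8
    ky <- (p[dn, lf] + 2 * p[dn, ctr_x] + p[dn, rt] -
           p[up, lf] - 2 * p[up, ctr_x] - p[up, rt]) / 8
    mag <- sqrt(kx^2 + ky^2)
    sel <- mag > best_mag
    best_mag[sel] <- mag[sel]
    gx[sel] <- kx[sel]
    gy[sel] <- ky[sel]
  }
  list(gx = gx, gy = gy, mag = best_mag)
}

#' Pyramid of oriented-gradient histograms
#'
#' Level `k` of the pyramid splits the image into `2^k` x `2^k` sub-images by
#' recursive quartering (level 0 is the whole image) and accumulates a
#' magnitude-weighted histogram of gradient orientations, folded to
#' `[0, 180)`, per sub-image. Gradients come from a 3x3 Sobel operator per RGB
#' channel; each pixel contributes the channel with the largest gradient
#' magnitude. Histograms are L1-normalized; gradient-free sub-images stay
#' all-zero and are flagged.
#'
#' @param img h x w x 3 RGB array in `[0, 1]`.
#' @param bins Number of orientation bins over `[0, 180)` (default 16).
#' @param max_level Deepest pyramid level (default 3, i.e. 64 sub-images).
#' @return List of class `hog_pyramid`: `levels` (list; level k+1 holds a
#'   `4^k` x `bins` matrix of histograms in row-major sub-image order),
#'   `zero` (per-level logical vectors flagging gradient-free sub-images),
#'   `bins`, `max_level`.
#' @export
hog_pyramid <- function(img, bins = 16, max_level = 3) {
  img <- as_rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < 2^(max_level + 1) || w < 2^(max_level + 1)) {
    stop("image too small: level-", max_level, " sub-images must be >= 2x2 pixels")
  }
  g <- .gradient_field(img)
  theta <- (atan2(g$gy, g$gx) * 180 / pi) %% 180
  bin <- pmin(floor(theta / (180 / bins)) + 1L, bins)

  levels <- vector("list", max_level + 1L)
  zero <- vector("list", max_level + 1L)
  for (lv in 0:max_level) {
    nsub <- 2^lv
    # half-open pixel ranges per sub-image (row-major over the grid)
    rcut <- floor(seq(0, h, length.out = nsub + 1L))
    ccut <- floor(seq(0, w, length.out = nsub + 1L))
    hm <- matrix(0, nsub * nsub, bins)
    for (i in seq_len(nsub)) {
      for (j in seq_len(nsub)) {
        rows <- (rcut[i] + 1L):rcut[i + 1L]
        cols <- (ccut[j] + 1L):ccut[j + 1L]
        b <- bin[rows, cols]
        m <- g$mag[rows, cols]
        hm[(i - 1L) * nsub + j, ] <- vapply(seq_len(bins), function(k) {
          sum(m[b == k])
        }, numeric(1))
      }
    }
    s <- rowSums(hm)
    zero[[lv + 1L]] <- s == 0
    hm[s > 0, ] <- hm[s > 0, , drop = FALSE] / s[s > 0]
    levels[[lv + 1L]] <- hm
  }
  structure(list(levels = levels, zero = zero, bins = bins,
                 max_level = max_level, mean_mag = mean(g$mag)),
            class = "hog_pyramid")
}

#' Histogram-intersection self-similarity of an image
#'
#' Histogram intersection kernel `HIK(h, g) = sum_i min(h_i, g_i)` between
#' each level-3 sub-image histogram and the whole-image (level-0) histogram,
#' aggregated as the median over the sub-images. Lies in `[0, 1]` for
#' L1-normalized histograms; 1 means every sub-image repeats the global
#' orientation structure.
#'
#' @param p A [hog_pyramid()] with levels 0 and 3 (or `max_level`).
#' @param level Pyramid level to compare against level 0 (default the deepest).
#' @return Value in `[0, 1]`, or `NA` if the image is gradient-free.
#' @export
self_similarity <- function(p, level = p$max_level) {
  stopifnot(inherits(p, "hog_pyramid"), level <= p$max_level)
  if (p$zero[[1]][1]) {
    warning("gradient-free image: self-similarity undefined")
    return(NA_real_)
  }
  g0 <- p$levels[[1]][1, ]
  sub <- p$levels[[level + 1L]]
  hik <- vapply(seq_len(nrow(sub)), function(i) sum(pmin(sub[i, ], g0)),
                numeric(1))
  stats::median(hik)
}

#' Mean gradient magnitude (complexity) of an image
#'
#' Mean over all pixels of the per-pixel gradient magnitude (the
#' maximum-across-channels Sobel magnitude, same gradient field as
#' [hog_pyramid()]), reported on the 0-255 intensity scale. Zero iff the image
#' is constant.
#'
#' @param img h x w x 3 RGB array in `[0, 1]`.
#' @return Non-negative mean gradient norm.
#' @export
complexity <- function(img) {
  mean(.gradient_field(img)$mag)
}

#' Anisotropy of the oriented-gradient distribution
#'
#' Variance of the pooled bin values of all level-3 histograms: uniform
#' orientation content gives 0, a single dominant orientation the maximum.
#'
#' @param p A [hog_pyramid()].
#' @param level Pyramid level to pool (default the deepest).
#' @return Non-negative variance (0, with a warning, for a gradient-free image).
#' @export
anisotropy <- function(p, level = p$max_level) {
  stopifnot(inherits(p, "hog_pyramid"), level <= p$max_level)
  vals <- as.vector(p$levels[[level + 1L]])
  if (all(p$zero[[level + 1L]])) {
    warning("gradient-free image: anisotropy 0 by convention")
    return(0)
  }
  stats::var(vals)
}

#' Birkhoff-like order/complexity ratio
#'
#' @param self_similarity Self-similarity value in `[0, 1]`.
#' @param complexity Mean gradient magnitude (> 0 for a defined ratio).
#' @return `self_similarity / complexity`, or `NA` (with a warning) when
#'   complexity is 0.
#' @export
birkhoff <- function(self_similarity, complexity) {
  if (is.na(complexity) || complexity == 0) {
    warning("complexity is 0: Birkhoff ratio undefined")
    return(NA_real_)
  }
  self_similarity / complexity
}

#' All four complexity descriptors of an image
#'
#' @param img h x w x 3 RGB array in `[0, 1]`.
#' @param bins,max_level Passed to [hog_pyramid()].
#' @return List of class `complexity_report`: `self_similarity`, `complexity`,
#'   `anisotropy`, `birkhoff`.
#' @export
complexity_report <- function(img, bins = 16, max_level = 3) {
  p <- hog_pyramid(img, bins = bins, max_level = max_level)
  cx <- p$mean_mag
  ss <- if (p$zero[[1]][1]) NA_real_ else self_similarity(p)
  an <- if (all(p$zero[[max_level + 1L]])) 0 else anisotropy(p)
  bk <- if (cx == 0) NA_real_ else ss / cx
  structure(list(self_similarity = ss, complexity = cx,
                 anisotropy = an, birkhoff = bk),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf(paste0("complexity report: self-similarity %.3f, complexity %.3f,",
                     " anisotropy %.3g, Birkhoff %.3g\n"),
              x$self_similarity, x$complexity, x$anisotropy, x$birkhoff))
  invisible(x)
}

#' @rdname complexity_report
#' @param x A `complexity_report`.
#' @param row.names,optional,... Passed over from the generic; unused.
#' @export
as.data.frame.complexity_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(`Self-Similarity` = x$self_similarity, Complexity = x$complexity,
             Anisotropy = x$anisotropy, `Birkhoff Metric` = x$birkhoff,
             check.names = FALSE, row.names = row.names)
}
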