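# Nearest-colour palette segmentation (look-up-table recolouring) and the
# per-RGB-plane correlation fidelity measure.

#' Segment an image with a palette by nearest colour
#'
#' Every pixel is assigned the palette colour minimizing the distance to it;
#' ties go to the lowest palette index. Distances are Euclidean Delta E*ab in
#' CIELAB by default (the analysis lives in CIELAB); `space = "rgb"` measures
#' Euclidean distance between sRGB triplets instead, as a sensitivity mode.
#'
#' @param lab CIELAB image array (h x w x 3).
#' @param palette A `relevant_palette`.
#' @param space `"lab"` (default) or `"rgb"`.
#' @return List of class `segmented_image`: `index` (h x w matrix of palette
#'   indices), `palette`, `rendered` (h x w x 3 sRGB array), `lab` (h x w x 3
#'   CIELAB array of assigned colours).
#' @export
segment_with_palette <- function(lab, palette, space = c("lab", "rgb")) {
  space <- match.arg(space)
  d <- dim(lab)
  if (is.null(d) || length(d) != 3L) stop("lab must be an image array")
  px <- matrix(lab, ncol = 3L)
  pal_lab <- palette$colors
  if (space == "lab") {
    dist <- delta_e_cross(px, pal_lab)
  } else {
    pal_rgb <- lab_to_srgb(pal_lab, clip = TRUE)
    px_rgb <- lab_to_srgb(px, clip = TRUE)
    dist <- delta_e_cross(px_rgb, pal_rgb)  # plain Euclidean on triplets
  }
  idx <- max.col(-dist, ties.method = "first")
  lab_out <- array(pal_lab[idx, ], dim = d)
  rendered <- array(lab_to_srgb(pal_lab, clip = TRUE)[idx, ], dim = d)
  structure(list(index = matrix(idx, d[1], d[2]), palette = palette,
                 rendered = rendered, lab = lab_out),
            class = "segmented_image")
}

#' @export
print.segmented_image <- function(x, ...) {
  cat(sprintf("segmented image %d x %d, %d palette colour(s), %d used\n",
              nrow(x$index), ncol(x$index), x$palette$size,
              length(unique(as.vector(x$index)))))
  invisible(x)
}

#' Per-channel correlation between an image and its segmented version
#'
#' Pearson correlation between each RGB colour plane of the original and the
#' segmented image, plus their arithmetic mean — the headline segmentation
#' fidelity number. A constant plane has no defined correlation; it is
#' returned as `NA`, excluded from the mean, and flagged with a warning.
#'
#' @param original,segmented h x w x 3 RGB arrays of equal dimensions (pass
#'   `segmented$rendered` for a [segment_with_palette()] result).
#' @return List with `r` (named length-3 vector) and `mean_r`.
#' @export
plane_correlation <- function(original, segmented) {
  if (inherits(segmented, "segmented_image")) segmented <- segmented$rendered
  if (!identical(dim(original), dim(segmented))) {
    stop("images must have identical dimensions")
  }
  r <- vapply(1:3, function(k) {
    a <- as.vector(original[, , k]); b <- as.vector(segmented[, , k])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, numeric(1))
  names(r) <- c("R", "G", "B")
  if (anyNA(r)) {
    warning("constant colour plane(s) excluded from the mean: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  }
  list(r = r, mean_r = mean(r, na.rm = TRUE))
}
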