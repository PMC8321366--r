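# The palette container: an ordered set of relevant colours in CIELAB with
# provenance (computational or subjective) and per-colour source locations.

#' Construct a relevant-colour palette
#'
#' @param lab n x 3 matrix of CIELAB colours (ordered).
#' @param provenance `"computational"` or `"subjective"`.
#' @param source Optional per-colour source information (e.g. a data frame of
#'   pixel coordinates), recycled/indexed parallel to the colours.
#' @return Object of class `relevant_palette`.
#' @export
new_palette <- function(lab, provenance = c("computational", "subjective"),
                        source = NULL) {
  provenance <- match.arg(provenance)
  lab <- .as_color_matrix(lab)$m
  if (nrow(lab) < 1L) stop("a palette needs at least one colour")
  colnames(lab) <- c("L", "a", "b")
  structure(list(colors = lab, provenance = provenance, source = source,
                 size = nrow(lab)),
            class = "relevant_palette")
}

#' @export
print.relevant_palette <- function(x, ...) {
  cat(sprintf("relevant palette (%s): %d colour(s)\n", x$provenance, x$size))
  print(utils::head(round(x$colors, 2), 10))
  if (x$size > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
length.relevant_palette <- function(x) x$size

#' Palette colours as sRGB hex strings
#' @param palette A `relevant_palette`.
#' @return Character vector of `#RRGGBB` values (gamut-clipped).
#' @export
palette_hex <- function(palette) {
  rgb <- lab_to_srgb(palette$colors, clip = TRUE)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3])
}

#' Overlap between two palettes
#'
#' Three complementary measures of agreement between a computational and a
#' subjective palette: the fraction of subjective colours lying within `tol`
#' Delta E*ab of at least one computational colour, the symmetric counterpart,
#' and the intersection-over-union of the two palettes' convex-hull areas in
#' the (a*, b*) plane. The hull measure needs at least 3 non-collinear colours
#' per palette and is `NA` otherwise.
#'
#' @param computational,subjective `relevant_palette` objects.
#' @param tol Matching tolerance in Delta E*ab.
#' @return List with `subjective_covered`, `computational_covered`,
#'   `hull_area_iou`.
#' @export
palette_overlap <- function(computational, subjective, tol = 10) {
  cc <- computational$colors
  sc <- subjective$colors
  d <- delta_e_cross(sc, cc)
  subj_cov <- mean(apply(d, 1, min) <= tol)
  comp_cov <- mean(apply(d, 2, min) <= tol)

  iou <- NA_real_
  h1 <- .ccw_hull(cc[, 2:3, drop = FALSE])
  h2 <- .ccw_hull(sc[, 2:3, drop = FALSE])
  if (!is.null(h1) && !is.null(h2)) {
    inter <- convex_polygon_intersection(h1, h2)
    ai <- if (nrow(inter) >= 3L) polygon_area(inter) else 0
    au <- polygon_area(h1) + polygon_area(h2) - ai
    iou <- if (au > 0) ai / au else NA_real_
  }
  list(subjective_covered = subj_cov,
       computational_covered = comp_cov,
       hull_area_iou = iou)
}
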