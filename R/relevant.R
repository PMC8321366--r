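# The two routes to a relevant-colour palette: aggregation of observer clicks
# (subjective) and density-ranked extraction from the CIELAB histogram with
# lightness/chroma gates (computational), plus hue/chroma tables.

#' Configuration for computational relevant-colour extraction
#'
#' @param delta_e_min Minimum CIELAB difference between palette entries; must
#'   exceed 1 (the discernibility unit).
#' @param L_range Admissible lightness interval `[L_low, L_high]`.
#' @param chroma_min Minimum chroma `C*ab` of a palette entry.
#' @param density_min Minimum fraction of image pixels a candidate must
#'   represent, in `[0, 1)`. A candidate's density is the pixel mass within
#'   `density_radius` Delta E*ab of its colour, so that noise spreading one
#'   paint over many unit cells still counts toward that paint.
#' @param density_radius Radius (Delta E*ab) of the neighbourhood over which
#'   candidate density is measured (default 7.5).
#' @return List of class `palette_config`.
#' @export
palette_config <- function(delta_e_min = 15, L_range = c(5, 95),
                           chroma_min = 5, density_min = 0.001,
                           density_radius = 7.5) {
  stopifnot(delta_e_min > 1, length(L_range) == 2L, L_range[1] < L_range[2],
            chroma_min >= 0, density_min >= 0, density_min < 1,
            density_radius > 0)
  structure(list(delta_e_min = delta_e_min, L_range = L_range,
                 chroma_min = chroma_min, density_min = density_min,
                 density_radius = density_radius),
            class = "palette_config")
}

#' Average the colour around an observer click
#'
#' An observer selection is the mean CIELAB colour of the 25 pixels in the
#' centred 5 x 5 window around the clicked pixel. The window must lie fully
#' inside the image: clicks at the border are rejected (observers select
#' chromatic areas, not edges).
#'
#' @param lab CIELAB image array (h x w x 3).
#' @param x,y Click position: column and row, 1-based.
#' @return List of class `selection` with `x`, `y`, and `color` (length-3
#'   CIELAB vector).
#' @export
aggregate_click <- function(lab, x, y) {
  d <- dim(lab)
  if (is.null(d) || length(d) != 3L) stop("lab must be an image array")
  h <- d[1]; w <- d[2]
  x <- as.integer(x); y <- as.integer(y)
  if (x < 3L || x > w - 2L || y < 3L || y > h - 2L) {
    stop("the 5x5 window around (", x, ", ", y,
         ") crosses the image border; select a point further inside")
  }
  win <- lab[(y - 2L):(y + 2L), (x - 2L):(x + 2L), , drop = FALSE]
  structure(list(x = x, y = y, color = apply(win, 3, mean)),
            class = "selection")
}

# occupied unit-cell statistics of a Lab image: count and mean colour per cell
.cell_stats <- function(px) {
  cells <- floor(px)
  key <- paste(cells[, 1], cells[, 2], cells[, 3], sep = ",")
  idx <- match(key, unique(key))
  n <- tabulate(idx)
  means <- cbind(
    L = rowsum(px[, 1], idx)[, 1] / n,
    a = rowsum(px[, 2], idx)[, 1] / n,
    b = rowsum(px[, 3], idx)[, 1] / n)
  first <- !duplicated(idx)
  list(cell = cells[first, , drop = FALSE][order(unique(idx)), , drop = FALSE],
       count = n, mean = means)
}

#' Extract the computational relevant colours of an image
#'
#' Density-ranked greedy selection over the unit-cell CIELAB histogram:
#' occupied cells are ranked by pixel count (ties broken by lexicographic
#' (L, a, b) cell index); scanning down the ranking, a cell's mean colour is
#' accepted when it passes the lightness and chroma gates, represents at
#' least `density_min` of the image pixels, and lies at least `delta_e_min`
#' Delta E*ab from every already-accepted colour. A candidate's density is
#' the pixel mass within `density_radius` of its mean colour (noise spreads
#' one paint across neighbouring unit cells; the mass belongs to the paint,
#' not to any single cell). Deterministic given image and configuration.
#'
#' @param lab CIELAB image array or n x 3 pixel matrix.
#' @param config A [palette_config()].
#' @return A `relevant_palette` with provenance `"computational"`; the source
#'   field records each entry's unit cell and pixel share.
#' @export
extract_relevant_colors <- function(lab, config = palette_config()) {
  px <- .lab_pixels(lab)
  if (nrow(px) == 0L) stop("empty image")
  cs <- .cell_stats(px)
  ord <- order(-cs$count, cs$cell[, 1], cs$cell[, 2], cs$cell[, 3])
  pol <- lab_to_polar(cs$mean)
  n <- nrow(px)

  neigh_density <- function(mu) {
    d <- delta_e_cross(matrix(mu, 1), cs$mean)[1, ]
    sum(cs$count[d <= config$density_radius]) / n
  }

  accepted <- integer(0)
  density <- numeric(0)
  for (i in ord) {
    mu <- cs$mean[i, ]
    if (mu[1] < config$L_range[1] || mu[1] > config$L_range[2]) next
    if (pol[i, "chroma"] < config$chroma_min) next
    if (length(accepted) &&
        min(delta_e_cross(matrix(mu, 1), cs$mean[accepted, , drop = FALSE])) <
          config$delta_e_min) next
    dens <- neigh_density(mu)
    if (dens < config$density_min) next
    accepted <- c(accepted, i)
    density <- c(density, dens)
  }
  if (!length(accepted)) stop("no relevant colours under this configuration")
  new_palette(cs$mean[accepted, , drop = FALSE], "computational",
              source = data.frame(cell_L = cs$cell[accepted, 1],
                                  cell_a = cs$cell[accepted, 2],
                                  cell_b = cs$cell[accepted, 3],
                                  density = density))
}

#' Build a subjective palette from observer selections
#'
#' Each selection counts as one relevant colour by default: observers were free
#' to pick equally or similarly relevant colours at different spatial
#' locations, and counts treat every choice as an entry. Optional merging
#' collapses selections closer than `merge_delta_e` by single-linkage
#' clustering, replacing each cluster with its mean colour.
#'
#' @param selections A list of `selection` objects (see [aggregate_click()]),
#'   or a data frame with columns `L`, `a`, `b` (and optionally `x`, `y`).
#' @param merge_delta_e `NULL` (no merging, the default) or a Delta E*ab
#'   threshold.
#' @return A `relevant_palette` with provenance `"subjective"`.
#' @export
subjective_palette <- function(selections, merge_delta_e = NULL) {
  if (is.data.frame(selections)) {
    stopifnot(all(c("L", "a", "b") %in% names(selections)))
    lab <- as.matrix(selections[, c("L", "a", "b")])
    src <- selections[, intersect(c("x", "y"), names(selections)), drop = FALSE]
  } else {
    if (!length(selections)) stop("at least one selection is required")
    lab <- t(vapply(selections, function(s) s$color, numeric(3)))
    src <- data.frame(x = vapply(selections, `[[`, 0L, "x"),
                      y = vapply(selections, `[[`, 0L, "y"))
  }
  if (nrow(lab) == 0L) stop("at least one selection is required")

  if (!is.null(merge_delta_e) && nrow(lab) > 1L) {
    tree <- stats::hclust(stats::dist(lab), method = "single")
    grp <- stats::cutree(tree, h = merge_delta_e)
    lab <- do.call(rbind, lapply(split(seq_along(grp), grp), function(ix) {
      colMeans(lab[ix, , drop = FALSE])
    }))
    src <- NULL
  }
  new_palette(lab, "subjective", source = src)
}

#' Hue/chroma decomposition and histograms
#'
#' Polar decomposition of each colour plus binned histograms: hue in
#' `hue_bin`-degree bins over `[0, 360)` and chroma in unit-width bins.
#' Achromatic colours are flagged and excluded from the hue histogram.
#'
#' @param x A `relevant_palette` or a CIELAB image array / pixel matrix.
#' @param hue_bin Hue bin width in degrees (default 10).
#' @return List with `table` (data frame: hue, chroma, achromatic),
#'   `hue_hist` and `chroma_hist` (data frames of bin edges and counts).
#' @export
hue_chroma_table <- function(x, hue_bin = 10) {
  lab <- if (inherits(x, "relevant_palette")) x$colors else .lab_pixels(x)
  pol <- lab_to_polar(lab)
  tab <- data.frame(hue = pol[, "hue"], chroma = pol[, "chroma"],
                    achromatic = pol[, "achromatic"] == 1)
  hb <- seq(0, 360, by = hue_bin)
  hidx <- pmin(floor(tab$hue[!tab$achromatic] / hue_bin) + 1L, length(hb) - 1L)
  hcounts <- tabulate(hidx, nbins = length(hb) - 1L)
  cmax <- max(1, ceiling(max(tab$chroma)))
  cidx <- pmin(floor(tab$chroma) + 1L, cmax)
  ccounts <- tabulate(cidx, nbins = cmax)
  list(table = tab,
       hue_hist = data.frame(start = hb[-length(hb)], end = hb[-1],
                             count = hcounts),
       chroma_hist = data.frame(start = 0:(cmax - 1), end = 1:cmax,
                                count = ccounts))
}
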