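# Per-image colourimetric gamut descriptors: discernible-colour counts on a
# unit CIELAB grid, colour volume, and the least-squares gamut ellipse in the
# (a*, b*) plane.

#' Count discernible colours of an image
#'
#' Segments colour space into half-open unit cells (`floor()` of each
#' coordinate) and counts the occupied cells: colours whose difference is at or
#' below ~1 CIELAB unit share a cell and are treated as indiscernible.
#' `"lab-3d"` bins (L*, a*, b*) on unit cubes; `"ab-2d"` bins the (a*, b*)
#' projection on unit squares.
#'
#' @param lab CIELAB image array or n x 3 pixel matrix.
#' @param mode `"lab-3d"` (default) or `"ab-2d"`.
#' @return Integer count of occupied cells.
#' @export
count_discernible_colors <- function(lab, mode = c("lab-3d", "ab-2d")) {
  mode <- match.arg(mode)
  px <- .lab_pixels(lab)
  if (nrow(px) == 0L) stop("empty image")
  cells <- floor(px)
  if (mode == "ab-2d") cells <- cells[, 2:3, drop = FALSE]
  nrow(unique(cells))
}

#' Colour volume of an image
#'
#' Default: volume of the convex hull of the CIELAB pixel cloud (cubic CIELAB
#' units). `mode = "cells"` instead counts occupied unit cubes (the 3-D
#' discernible-colour count), useful for sensitivity analysis. Degenerate
#' clouds (all pixels coplanar or fewer than 4 distinct colours) have volume 0
#' and are flagged.
#'
#' @param lab CIELAB image array or n x 3 pixel matrix.
#' @param mode `"hull"` (default) or `"cells"`.
#' @return List with `volume` and `degenerate`.
#' @export
gamut_volume <- function(lab, mode = c("hull", "cells")) {
  mode <- match.arg(mode)
  px <- .lab_pixels(lab)
  if (nrow(px) == 0L) stop("empty image")
  if (mode == "cells") {
    return(list(volume = count_discernible_colors(px, "lab-3d"),
                degenerate = FALSE))
  }
  convex_hull_volume(px)
}

#' Fit an ellipse to the (a*, b*) gamut by direct least squares
#'
#' Ellipse-constrained conic fit (the stable partitioned formulation of the
#' direct least-squares method), guaranteed to return an ellipse rather than
#' another conic. Data are centred and isotropically scaled before the fit for
#' numerical conditioning.
#'
#' @param lab CIELAB image array, n x 3 pixel matrix, or an n x 2 matrix of
#'   (a*, b*) coordinates.
#' @return List of class `gamut_ellipse`: `center` (a*, b*), `semi_major`,
#'   `semi_minor`, `angle` (orientation of the longer axis from +a*, degrees in
#'   `[0, 180)`), `area`, `axis_ratio`.
#' @export
fit_gamut_ellipse <- function(lab) {
  m <- if (is.matrix(lab) && ncol(lab) == 2L) lab else .lab_pixels(lab)[, 2:3, drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(unique(m)) < 5L) stop("ellipse fit needs at least 5 distinct (a*, b*) points")
  mu <- colMeans(m)
  s <- mean(apply(m, 2, stats::sd))
  if (s == 0) stop("degenerate (a*, b*) scatter: zero variance")
  x <- (m[, 1] - mu[1]) / s
  y <- (m[, 2] - mu[2]) / s

  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  tmat <- -solve(s3, t(s2))
  mm <- s1 + s2 %*% tmat
  mm <- rbind(mm[3, ] / 2, -mm[2, ], mm[1, ] / 2)
  ev <- eigen(mm)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("degenerate conic: no ellipse solution")
  a1 <- vec[, ok[1]]
  coef <- c(a1, as.vector(tmat %*% a1))  # A B C D E F in scaled coords

  # geometric parameters in scaled coords
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(q, symmetric = TRUE)
  ax2 <- -fc / eq$values
  if (any(ax2 <= 0)) stop("degenerate conic: non-positive axis")
  axes <- sqrt(ax2)
  imaj <- which.max(axes)
  vmaj <- eq$vectors[, imaj]
  angle <- (atan2(vmaj[2], vmaj[1]) * 180 / pi) %% 180

  semi_major <- max(axes) * s
  semi_minor <- min(axes) * s
  structure(list(
    center = c(a = cx * s + mu[1], b = cy * s + mu[2]),
    semi_major = semi_major,
    semi_minor = semi_minor,
    angle = angle,
    area = pi * semi_major * semi_minor,
    axis_ratio = semi_minor / semi_major),
    class = "gamut_ellipse")
}

#' @export
print.gamut_ellipse <- function(x, ...) {
  cat(sprintf(
    "gamut ellipse: center (%.2f, %.2f), semi-axes %.2f / %.2f, angle %.1f deg, area %.1f\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor, x$angle, x$area))
  invisible(x)
}

#' Summarize the colour gamut of an image
#'
#' Assembles the per-image descriptors: discernible-colour count (unit cubes in
#' CIELAB by default), convex-hull colour volume, the fitted (a*, b*) gamut
#' ellipse, and channel means. A degenerate point cloud yields volume 0 and a
#' `NULL` ellipse with the failure reason recorded.
#'
#' @param lab CIELAB image array or n x 3 pixel matrix.
#' @param ndc_mode Binning mode for [count_discernible_colors()].
#' @return List of class `gamut_summary` with fields `n_discernible`, `volume`,
#'   `volume_degenerate`, `ellipse` (or `NULL`), `ellipse_error`, `mean_L`,
#'   `mean_a`, `mean_b`.
#' @export
summarize_gamut <- function(lab, ndc_mode = c("lab-3d", "ab-2d")) {
  ndc_mode <- match.arg(ndc_mode)
  px <- .lab_pixels(lab)
  if (nrow(px) == 0L) stop("empty image")
  vol <- gamut_volume(px)
  ell <- tryCatch(fit_gamut_ellipse(px), error = function(e) e)
  failed <- inherits(ell, "error")
  structure(list(
    n_discernible = count_discernible_colors(px, ndc_mode),
    volume = vol$volume,
    volume_degenerate = vol$degenerate,
    ellipse = if (failed) NULL else ell,
    ellipse_error = if (failed) conditionMessage(ell) else NA_character_,
    mean_L = mean(px[, 1]),
    mean_a = mean(px[, 2]),
    mean_b = mean(px[, 3])),
    class = "gamut_summary")
}

#' @export
print.gamut_summary <- function(x, ...) {
  cat("gamut summary\n")
  cat(sprintf("  discernible colours: %d\n", x$n_discernible))
  cat(sprintf("  volume: %.1f%s\n", x$volume,
              if (x$volume_degenerate) " (degenerate)" else ""))
  cat(sprintf("  mean L*/a*/b*: %.1f / %.1f / %.1f\n", x$mean_L, x$mean_a, x$mean_b))
  if (is.null(x$ellipse)) cat("  ellipse: <", x$ellipse_error, ">\n")
  else print(x$ellipse)
  invisible(x)
}

#' One-row data frame of gamut descriptors (report layout)
#'
#' Column names follow the usual reporting abbreviations: NDC, L*, a*, b*,
#' Angle, Ratio, Area, Volume.
#'
#' @param x A `gamut_summary`.
#' @param row.names,optional,... Passed over from the generic; unused.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.gamut_summary <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    NDC = x$n_discernible,
    `L*` = x$mean_L, `a*` = x$mean_a, `b*` = x$mean_b,
    Angle = if (is.null(x$ellipse)) NA_real_ else x$ellipse$angle,
    Ratio = if (is.null(x$ellipse)) NA_real_ else x$ellipse$axis_ratio,
    Area = if (is.null(x$ellipse)) NA_real_ else x$ellipse$area,
    Volume = x$volume,
    check.names = FALSE, row.names = row.names)
}
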