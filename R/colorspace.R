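# sRGB (IEC 61966-2-1, D65) <-> CIELAB (D65, 2 deg observer), plus the polar
# chroma/hue form and the RG/BY opponent plane used for colour-direction angles.
#
# Conversions are authored here in double precision: palette extraction and the
# discernible-colour binning both live on a unit-Delta-E grid, so the chain
# sRGB -> XYZ -> CIELAB and its analytic inverse must round-trip far below 1 JND.

# sRGB -> XYZ (linear RGB, D65 primaries). White point = rowSums(.srgb_m),
# i.e. (1,1,1) maps to L*=100, a*=b*=0 exactly.
.srgb_m <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.srgb_minv <- solve(.srgb_m)
.srgb_white <- rowSums(.srgb_m)

.lab_delta <- 6 / 29

#' Coerce colour input to an n x 3 matrix
#'
#' Accepts an h x w x 3 image array, an n x 3 matrix/data.frame, or a length-3
#' vector. Returns the n x 3 matrix together with the original dimensions so
#' image-shaped output can be restored.
#' @noRd
.as_color_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    if (d[3] != 3L) stop("image array must have 3 channels")
    return(list(m = matrix(x, ncol = 3L), dim = d))
  }
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("colour vector must have length 3")
    x <- matrix(x, ncol = 3L)
  }
  if (ncol(x) != 3L) stop("colour matrix must have 3 columns")
  list(m = x, dim = NULL)
}

.restore_shape <- function(m, dim) {
  if (is.null(dim)) m else array(m, dim = dim)
}

#' Convert sRGB colours to CIELAB
#'
#' Standard sRGB decoding: per-channel inverse companding, linear-RGB to XYZ
#' under the D65 white point, then CIELAB (2 deg observer). Channel values must
#' already be in `[0, 1]` (divide 8-bit codes by 255).
#'
#' @param x An h x w x 3 image array, an n x 3 matrix, or a length-3 vector of
#'   sRGB values in `[0, 1]`.
#' @return CIELAB values (`L*` in 0-100) in the same shape as the input.
#' @examples
#' srgb_to_lab(c(1, 1, 1))   # L* = 100, a* = b* = 0
#' srgb_to_lab(c(0, 0, 0))   # black
#' @export
srgb_to_lab <- function(x) {
  cm <- .as_color_matrix(x)
  m <- cm$m
  if (anyNA(m)) stop("RGB values must not be NA")
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9) {
    stop("RGB channel values out of range [0, 1]: range is [",
         format(min(m)), ", ", format(max(m)), "]")
  }
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_m)
  r <- sweep(xyz, 2, .srgb_white, "/")
  f <- ifelse(r > .lab_delta^3, r^(1 / 3), r / (3 * .lab_delta^2) + 4 / 29)
  lab <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3]))
  .restore_shape(lab, cm$dim)
}

#' Convert CIELAB colours to sRGB
#'
#' Analytic inverse of [srgb_to_lab()]. Out-of-gamut colours yield channel
#' values outside `[0, 1]`; they are returned as-is unless `clip = TRUE`, so
#' callers can test gamut membership (see [in_srgb_gamut()]).
#'
#' @param x CIELAB values in the shapes accepted by [srgb_to_lab()].
#' @param clip Clip the result into `[0, 1]`?
#' @return sRGB values in the same shape as the input.
#' @export
lab_to_srgb <- function(x, clip = FALSE) {
  cm <- .as_color_matrix(x)
  lab <- cm$m
  fy <- (lab[, 1] + 16) / 116
  f <- cbind(fy + lab[, 2] / 500, fy, fy - lab[, 3] / 200)
  r <- ifelse(f > .lab_delta, f^3, 3 * .lab_delta^2 * (f - 4 / 29))
  xyz <- sweep(r, 2, .srgb_white, "*")
  lin <- xyz %*% t(.srgb_minv)
  m <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  if (clip) m <- pmin(pmax(m, 0), 1)
  colnames(m) <- c("R", "G", "B")
  .restore_shape(m, cm$dim)
}

#' Test whether CIELAB colours lie inside the sRGB gamut
#'
#' @param lab CIELAB colours (matrix or vector).
#' @param tol Slack on the `[0, 1]` channel bounds.
#' @return Logical vector, one entry per colour.
#' @export
in_srgb_gamut <- function(lab, tol = 1e-9) {
  rgb <- .as_color_matrix(lab_to_srgb(lab))$m
  rowSums(rgb < -tol | rgb > 1 + tol) == 0
}

#' Euclidean CIELAB colour difference
#'
#' Delta E*ab between two colours, or between each row pair of two matrices.
#' @param x,y CIELAB colours (length-3 vectors or n x 3 matrices).
#' @return Numeric vector of colour differences.
#' @export
delta_e <- function(x, y) {
  xm <- .as_color_matrix(x)$m
  ym <- .as_color_matrix(y)$m
  sqrt(rowSums((xm - ym)^2))
}

#' Pairwise CIELAB distance matrix
#' @param x n x 3 CIELAB matrix.
#' @param y m x 3 CIELAB matrix (default `x`).
#' @return n x m matrix of Delta E*ab values.
#' @export
delta_e_cross <- function(x, y = x) {
  xm <- .as_color_matrix(x)$m
  ym <- .as_color_matrix(y)$m
  d2 <- outer(rowSums(xm^2), rep(1, nrow(ym))) +
    outer(rep(1, nrow(xm)), rowSums(ym^2)) - 2 * tcrossprod(xm, ym)
  sqrt(pmax(d2, 0))
}

#' Polar (chroma, hue) form of CIELAB colours
#'
#' Chroma `C*ab = sqrt(a*^2 + b*^2)` and hue angle `hab = atan2(b*, a*)` in
#' degrees counter-clockwise from the positive a* axis, folded to `[0, 360)`.
#' Achromatic colours (chroma 0) get hue 0 by convention and are flagged in the
#' `achromatic` column.
#'
#' @param lab CIELAB colours (vector, matrix, or image array).
#' @return A matrix with columns `chroma`, `hue`, `achromatic` (0/1).
#' @export
lab_to_polar <- function(lab) {
  m <- .as_color_matrix(lab)$m
  chroma <- unname(sqrt(m[, 2]^2 + m[, 3]^2))
  achrom <- chroma == 0
  hue <- ifelse(achrom, 0, (unname(atan2(m[, 3], m[, 2])) * 180 / pi) %% 360)
  cbind(chroma = chroma, hue = hue, achromatic = as.numeric(achrom))
}

#' Opponent-plane projection of RGB colours
#'
#' The red-green and blue-yellow opponent axes used for colour-direction
#' analysis: `RG = (R - G) / sqrt(2)` and `BY = (R + G - 2 B) / sqrt(6)`.
#' Applied to (non-linearized) sRGB channel values; greys map to the origin.
#'
#' @param x RGB colours in `[0, 1]` (vector, matrix, or image array).
#' @return Matrix with columns `RG` and `BY`.
#' @export
rgb_to_opponent <- function(x) {
  m <- .as_color_matrix(x)$m
  cbind(RG = (m[, 1] - m[, 2]) / sqrt(2),
        BY = (m[, 1] + m[, 2] - 2 * m[, 3]) / sqrt(6))
}

#' Colour angle in the opponent plane
#'
#' `theta = atan2(BY, RG)` in degrees. `fold = "signed"` reports angles in
#' `(-180, 180]`, `"full"` folds to `[0, 360)` (colours carry a sign), and
#' `"axis"` folds to `[0, 180)` (a principal colour axis has no sign).
#' Achromatic inputs (RG = BY = 0) have no direction: a single achromatic
#' colour is an error; in vector input they come back `NA` with a warning.
#'
#' @param op Opponent coordinates: a length-2 `(RG, BY)` vector or an n x 2
#'   matrix as produced by [rgb_to_opponent()].
#' @param fold One of `"signed"`, `"full"`, `"axis"`.
#' @return Angle(s) in degrees.
#' @examples
#' opponent_angle(rgb_to_opponent(c(1, 0, 0)))  # red: 30 degrees
#' opponent_angle(rgb_to_opponent(c(1, 1, 0)))  # yellow: 90 degrees
#' @export
opponent_angle <- function(op, fold = c("signed", "full", "axis")) {
  fold <- match.arg(fold)
  if (is.null(dim(op))) op <- matrix(op, ncol = 2L)
  achrom <- op[, 1] == 0 & op[, 2] == 0
  if (nrow(op) == 1L && achrom) {
    stop("achromatic colour: opponent angle undefined for RG = BY = 0")
  }
  if (any(achrom)) warning(sum(achrom), " achromatic colour(s): angle set to NA")
  th <- unname(atan2(op[, 2], op[, 1]) * 180 / pi)
  th <- switch(fold,
    signed = ifelse(th <= -180, th + 360, th),
    full = th %% 360,
    axis = th %% 180)
  th[achrom] <- NA_real_
  th
}
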