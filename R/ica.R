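# Efficient-coding analysis of image patches: random patch sampling, PCA
# whitening, fixed-point ICA (I = A s; columns of A are basis functions, rows
# of W = A^-1 are filters), energy ordering, and the preferred colour
# direction of each basis in the RG/BY opponent plane.

#' Sample random patches from images
#'
#' Draws `n_per_image` fully interior, possibly overlapping p x p patches at
#' uniformly random offsets from each image and flattens them to length-3p^2
#' vectors (channel-major: all R pixels, then G, then B). Images smaller than
#' the patch are skipped with a warning. Deterministic for a fixed seed.
#'
#' @param images A single RGB array or a list of them.
#' @param n_per_image Patches per image.
#' @param p Patch edge length in pixels (default 8).
#' @param seed Integer seed (mandatory: no hidden RNG state).
#' @return List of class `patch_set`: `X` (n x 3p^2 matrix, one patch per
#'   row), `p`, `source` (data frame: image, row offset, col offset), `seed`.
#' @export
sample_patches <- function(images, n_per_image, p = 8, seed) {
  if (missing(seed)) stop("a seed is required")
  if (!is.list(images)) images <- list(images)
  set.seed(seed)
  out <- list(); src <- list()
  for (ii in seq_along(images)) {
    img <- as_rgb_image(images[[ii]])
    h <- dim(img)[1]; w <- dim(img)[2]
    if (h < p || w < p) {
      warning("image ", ii, " smaller than patch size; skipped")
      next
    }
    ro <- sample.int(h - p + 1L, n_per_image, replace = TRUE)
    co <- sample.int(w - p + 1L, n_per_image, replace = TRUE)
    m <- t(vapply(seq_len(n_per_image), function(k) {
      as.vector(img[ro[k]:(ro[k] + p - 1L), co[k]:(co[k] + p - 1L), ])
    }, numeric(3 * p * p)))
    out[[length(out) + 1L]] <- m
    src[[length(src) + 1L]] <- data.frame(image = ii, row = ro, col = co)
  }
  if (!length(out)) stop("no image was large enough for the patch size")
  structure(list(X = do.call(rbind, out), p = p,
                 source = do.call(rbind, src), seed = seed),
            class = "patch_set")
}

#' PCA-whiten a patch set
#'
#' Centres the data and decorrelates it through the eigendecomposition of the
#' sample covariance so the output covariance is the identity. Directions with
#' eigenvalues below `tol` times the largest (or beyond `max_dim`) are
#' dropped, reducing to the numerical rank with a warning when rank-deficient.
#' The dewhitening map is stored so mixing vectors can be expressed back in
#' pixel space.
#'
#' @param patches A `patch_set` (or plain n x d matrix).
#' @param max_dim Optional cap on the retained dimensionality (standard PCA
#'   reduction before ICA).
#' @param tol Relative eigenvalue cutoff for the numerical rank.
#' @return List of class `whitened_patches`: `Z` (n x r whitened matrix),
#'   `whitening` (d x r map), `dewhitening` (r x d map), `mean` (length d),
#'   `rank`, `p`.
#' @export
whiten <- function(patches, max_dim = NULL, tol = 1e-12) {
  X <- if (inherits(patches, "patch_set")) patches$X else as.matrix(patches)
  p <- if (inherits(patches, "patch_set")) patches$p else NA_integer_
  n <- nrow(X); d <- ncol(X)
  if (n <= d && is.null(max_dim)) {
    stop("need more patches than dimensions (n > ", d, ")")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ev <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  vals <- ev$values
  keep <- which(vals > tol * max(vals, 0))
  if (!length(keep)) stop("degenerate patch set: covariance has rank 0")
  if (length(keep) < d) {
    warning("rank-deficient covariance: reducing to rank ", length(keep))
  }
  if (!is.null(max_dim)) keep <- keep[seq_len(min(max_dim, length(keep)))]
  V <- ev$vectors[, keep, drop = FALSE]
  sv <- sqrt(vals[keep])
  K <- V %*% diag(1 / sv, length(keep))          # d x r
  D <- diag(sv, length(keep)) %*% t(V)           # r x d, Xc ~ Z %*% D
  structure(list(Z = Xc %*% K, whitening = K, dewhitening = D, mean = mu,
                 rank = length(keep), p = p),
            class = "whitened_patches")
}

#' Fit independent components to whitened patches
#'
#' Fixed-point ICA with symmetric decorrelation on the whitened data (cubic /
#' kurtosis nonlinearity by default, `tanh` available), via the `ica` package
#' with a seed-derived orthonormal initial rotation, so runs are deterministic.
#' The estimated mixing matrix is mapped back through the dewhitening map, so
#' each column (basis function) lives in pixel space; basis energies are the
#' L2 norms of those columns.
#'
#' @param data A `whitened_patches` object.
#' @param n_components Number of components (default: the whitened rank).
#' @param seed Integer seed for the initial rotation.
#' @param fun Nonlinearity: `"kur"` (cubic, default) or `"tanh"`.
#' @param maxit,tol Iteration cap and convergence tolerance.
#' @return List of class `ica_basis_set`: `A` (d x m pixel-space mixing
#'   columns), `S` (n x m sources), `energy`, `p`, `mean`, plus `rank` and
#'   `direction` slots filled by [order_and_normalize()] and
#'   [basis_color_direction()].
#' @export
fit_ica <- function(data, n_components = data$rank, seed, fun = c("kur", "tanh"),
                    maxit = 500, tol = 1e-6) {
  stopifnot(inherits(data, "whitened_patches"))
  fun <- match.arg(fun)
  if (missing(seed)) stop("a seed is required")
  m <- n_components
  if (m > data$rank) stop("n_components exceeds the whitened dimension")
  set.seed(seed)
  R0 <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
  fit <- ica::icafast(data$Z, nc = m, center = TRUE, maxit = maxit, tol = tol,
                      Rmat = R0, alg = "par",
                      fun = if (fun == "kur") "kur" else "logcosh")
  if (!isTRUE(fit$converged)) {
    stop("ICA did not converge within ", maxit,
         " iterations (tolerance ", format(tol), "); the data may be",
         " Gaussian or otherwise non-identifiable")
  }
  # Z ~ S %*% t(M) in whitened coords; back to pixel space through dewhitening
  A <- t(data$dewhitening) %*% fit$M            # d x m
  energy <- sqrt(colSums(A^2))
  structure(list(A = A, S = fit$S, energy = energy, p = data$p,
                 mean = data$mean, rank = NULL, direction = NULL,
                 normalized = FALSE, iter = fit$iter),
            class = "ica_basis_set")
}

#' Order basis functions by energy and normalize them
#'
#' Sorts the basis columns by decreasing L2 norm (energy), keeping the
#' original relative order on ties (stable sort), then scales every column to
#' unit norm and records the ranks.
#'
#' @param bases An `ica_basis_set`.
#' @return The `ica_basis_set` with columns reordered and normalized, `rank`
#'   set to `1:m`, and the pre-normalization energies kept in `energy`.
#' @export
order_and_normalize <- function(bases) {
  stopifnot(inherits(bases, "ica_basis_set"))
  ord <- order(-bases$energy)   # radix sort: stable for ties
  A <- bases$A[, ord, drop = FALSE]
  energy <- bases$energy[ord]
  A <- sweep(A, 2, pmax(energy, .Machine$double.eps), "/")
  bases$A <- A
  bases$S <- bases$S[, ord, drop = FALSE]
  bases$energy <- energy
  bases$rank <- seq_along(energy)
  bases$normalized <- TRUE
  bases
}

#' Preferred colour direction of one basis function
#'
#' Treats a basis function as p^2 points in 3-D colour space, takes the first
#' principal component of that point cloud (the dominant colour-variation
#' axis), projects it onto the (RG, BY) opponent plane, and reports the angle,
#' folded to `[0, 180)` because a principal axis has no sign. Bases whose
#' opponent-plane projection is negligible relative to their colour variation
#' (achromatic or flat patches) have no chromatic direction and return `NA`.
#'
#' @param basis A length-3p^2 basis vector (one column of `A`).
#' @param p Patch edge length.
#' @param achromatic_tol Minimum ratio of opponent-plane magnitude to total
#'   axis magnitude for a defined direction.
#' @return Angle in degrees in `[0, 180)`, or `NA` for achromatic bases.
#' @export
basis_color_direction <- function(basis, p, achromatic_tol = 0.05) {
  pts <- matrix(basis, ncol = 3L)  # p^2 x 3, channel-major flattening
  pts <- sweep(pts, 2, colMeans(pts))
  tv <- sum(pts^2)
  if (tv < .Machine$double.eps) return(NA_real_)   # flat patch
  v <- svd(pts, nu = 0, nv = 1)$v[, 1]
  op <- c((v[1] - v[2]) / sqrt(2), (v[1] + v[2] - 2 * v[3]) / sqrt(6))
  if (sqrt(sum(op^2)) < achromatic_tol) return(NA_real_)  # achromatic axis
  (atan2(op[2], op[1]) * 180 / pi) %% 180
}

#' Colour directions of all bases in a set
#'
#' @param bases An `ica_basis_set`.
#' @param achromatic_tol Passed to [basis_color_direction()].
#' @return The `ica_basis_set` with `direction` filled (NA = achromatic).
#' @export
basis_directions <- function(bases, achromatic_tol = 0.05) {
  stopifnot(inherits(bases, "ica_basis_set"))
  bases$direction <- apply(bases$A, 2, basis_color_direction, p = bases$p,
                           achromatic_tol = achromatic_tol)
  bases
}

#' Histogram of colour-direction angles
#'
#' Counts angles per bin over `[0, 180)` for axis-valued basis directions
#' (`folded = TRUE`) or `[0, 360)` for vector-valued relevant-colour angles.
#' `NA` (achromatic) entries are excluded and reported in `n_achromatic`.
#'
#' @param angles Numeric vector of angles in degrees (NAs allowed).
#' @param bin_width Bin width in degrees (default 10).
#' @param folded Axis-valued angles over `[0, 180)`?
#' @return List of class `direction_histogram`: `bin_start`, `bin_end`,
#'   `counts`, `folded`, `n_achromatic`.
#' @export
direction_histogram <- function(angles, bin_width = 10, folded = TRUE) {
  span <- if (folded) 180 else 360
  n_ach <- sum(is.na(angles))
  a <- angles[!is.na(angles)] %% span
  edges <- seq(0, span, by = bin_width)
  if (edges[length(edges)] < span) edges <- c(edges, span)
  idx <- pmin(floor(a / bin_width) + 1L, length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_start = edges[-length(edges)], bin_end = edges[-1],
                 counts = counts, folded = folded, n_achromatic = n_ach),
            class = "direction_histogram")
}

#' @export
print.direction_histogram <- function(x, ...) {
  cat(sprintf("direction histogram over [0, %d): %d angle(s), %d achromatic\n",
              if (x$folded) 180L else 360L, sum(x$counts), x$n_achromatic))
  invisible(x)
}
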