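# Convex-hull geometry: 3-D hull volume (quickhull) for the CIELAB colour
# volume, and convex polygon intersection for gamut-area overlap.

#' Volume of the 3-D convex hull of a point cloud
#'
#' Quickhull over the unique points; the volume is the sum of signed
#' tetrahedron volumes of the outward-oriented hull facets. Degenerate clouds
#' (fewer than 4 unique points, collinear, or coplanar) have volume 0 and are
#' flagged.
#'
#' @param pts n x 3 numeric matrix.
#' @return List with `volume` and logical `degenerate`.
#' @export
convex_hull_volume <- function(pts) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  if (n < 4L) return(list(volume = 0, degenerate = TRUE))

  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) return(list(volume = 0, degenerate = TRUE))
  tol <- 1e-10 * scale

  # initial simplex: farthest pair among axis extremes, then farthest from the
  # line, then farthest from the plane
  ext <- unique(c(apply(pts, 2, which.min), apply(pts, 2, which.max)))
  dmax <- 0; i1 <- ext[1]; i2 <- ext[1]
  for (a in ext) for (b in ext) {
    d <- sum((pts[a, ] - pts[b, ])^2)
    if (d > dmax) { dmax <- d; i1 <- a; i2 <- b }
  }
  if (dmax < tol^2) return(list(volume = 0, degenerate = TRUE))
  u <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  ld <- rowSums(cr^2)
  i3 <- which.max(ld)
  if (ld[i3] < (tol * sqrt(sum(u^2)))^2) return(list(volume = 0, degenerate = TRUE))
  nrm <- .cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  pd <- as.vector(rel %*% nrm)
  i4 <- which.max(abs(pd))
  if (abs(pd[i4]) < tol) return(list(volume = 0, degenerate = TRUE))

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, .orient_face, pts = pts, interior = interior)

  # outside sets: for each live face, points strictly outside it
  assigned <- rep(FALSE, n)
  assigned[c(i1, i2, i3, i4)] <- TRUE
  face_pts <- vector("list", length(faces))
  cand <- which(!assigned)
  for (fi in seq_along(faces)) {
    if (!length(cand)) break
    d <- .face_dist(faces[[fi]], pts, cand)
    out <- cand[d > tol]
    face_pts[[fi]] <- out
    cand <- setdiff(cand, out)
  }

  repeat {
    fi <- which(vapply(face_pts, length, 1L) > 0L)
    if (!length(fi)) break
    fi <- fi[1]
    cps <- face_pts[[fi]]
    d <- .face_dist(faces[[fi]], pts, cps)
    p <- cps[which.max(d)]
    # visible faces
    vis <- which(vapply(seq_along(faces), function(k) {
      .face_dist(faces[[k]], pts, p) > tol
    }, logical(1)))
    # horizon: edges appearing in exactly one visible face
    edges <- do.call(rbind, lapply(vis, function(k) {
      f <- faces[[k]]$v
      rbind(sort(c(f[1], f[2])), sort(c(f[2], f[3])), sort(c(f[1], f[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    orphan <- unique(unlist(face_pts[vis]))
    orphan <- setdiff(orphan, p)
    keep <- setdiff(seq_along(faces), vis)
    faces <- faces[keep]
    face_pts <- face_pts[keep]
    for (e in seq_len(nrow(horizon))) {
      nf <- .orient_face(c(horizon[e, ], p), pts, interior)
      faces[[length(faces) + 1L]] <- nf
      if (length(orphan)) {
        d <- .face_dist(nf, pts, orphan)
        out <- orphan[d > tol]
        face_pts[[length(faces)]] <- out
        orphan <- setdiff(orphan, out)
      } else {
        face_pts[[length(faces)]] <- integer(0)
      }
    }
  }

  vol <- sum(vapply(faces, function(f) {
    v <- pts[f$v, , drop = FALSE]
    det(v) / 6
  }, numeric(1)))
  list(volume = abs(vol), degenerate = FALSE)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orient face vertices so the normal points away from the interior point
.orient_face <- function(v, pts, interior) {
  nrm <- .cross3(pts[v[2], ] - pts[v[1], ], pts[v[3], ] - pts[v[1], ])
  if (sum(nrm * (interior - pts[v[1], ])) > 0) {
    v <- v[c(1, 3, 2)]
    nrm <- -nrm
  }
  list(v = v, n = nrm, p0 = pts[v[1], ])
}

# signed distances (un-normalized scaled by |n|) of points idx from face plane
.face_dist <- function(face, pts, idx) {
  nn <- face$n / sqrt(sum(face$n^2))
  as.vector(sweep(pts[idx, , drop = FALSE], 2, face$p0) %*% nn)
}

#' Area of a convex polygon (shoelace)
#' @param poly n x 2 matrix of vertices in order.
#' @return Non-negative area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Intersection of two convex polygons (Sutherland-Hodgman)
#'
#' @param subject,clip Convex polygons as n x 2 matrices, vertices in
#'   counter-clockwise order.
#' @return The intersection polygon (possibly 0 rows).
#' @export
convex_polygon_intersection <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= 0
    inter <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2])
      d2 <- c(b[1] - a[1], b[2] - a[2])
      den <- d2[1] * d1[2] - d2[2] * d1[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / -den
      p + t * d1
    }
    res <- list()
    np <- nrow(out)
    for (j in seq_len(np)) {
      p <- out[j, ]; q <- out[if (j == np) 1L else j + 1L, ]
      pi <- inside(p); qi <- inside(q)
      if (pi && qi) res[[length(res) + 1L]] <- q
      else if (pi && !qi) res[[length(res) + 1L]] <- inter(p, q)
      else if (!pi && qi) { res[[length(res) + 1L]] <- inter(p, q); res[[length(res) + 1L]] <- q }
    }
    out <- if (length(res)) do.call(rbind, res) else matrix(numeric(0), ncol = 2L)
  }
  out
}

# counter-clockwise convex hull of 2-D points (signed-area corrected)
.ccw_hull <- function(xy) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3L) return(NULL)
  h <- grDevices::chull(xy)
  poly <- xy[h, , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (s < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  if (polygon_area(poly) == 0) return(NULL)
  poly
}
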