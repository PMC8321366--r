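# Naive reference implementations (no vectorized shortcuts) and small image
# constructors used as independent oracles across the suite.

random_rgb_image <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# 90-degree counter-clockwise rotation of an h x w x 3 array
rotate90 <- function(img) {
  d <- dim(img)
  out <- array(0, c(d[2], d[1], 3))
  for (k in 1:3) out[, , k] <- t(img[, , k])[d[2]:1, ]
  out
}

# brute-force discernible-colour count: insert floor-triplets into a set
oracle_ndc <- function(px, mode = "lab-3d") {
  seen <- character(0)
  for (i in seq_len(nrow(px))) {
    cell <- floor(px[i, ])
    if (mode == "ab-2d") cell <- cell[2:3]
    seen <- union(seen, paste(cell, collapse = "/"))
  }
  length(seen)
}

# brute-force nearest-palette assignment: check all palette distances per pixel
oracle_segment <- function(lab_img, pal_lab) {
  d <- dim(lab_img)
  idx <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    px <- lab_img[i, j, ]
    best <- Inf; bk <- 0L
    for (k in seq_len(nrow(pal_lab))) {
      dd <- sum((px - pal_lab[k, ])^2)
      if (dd < best - 1e-15) { best <- dd; bk <- k }
    }
    idx[i, j] <- bk
  }
  idx
}

# naive per-pixel HOG pyramid: replicate-padded 3x3 Sobel per channel,
# max-magnitude channel, orientations folded to [0,180), magnitude weights
oracle_hog <- function(img, bins = 16, max_level = 3) {
  img <- img * 255
  h <- dim(img)[1]; w <- dim(img)[2]
  at <- function(i, j, k) img[min(max(i, 1), h), min(max(j, 1), w), k]
  gx <- gy <- mag <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    bm <- -1
    for (k in 1:3) {
      sx <- (at(i - 1, j + 1, k) + 2 * at(i, j + 1, k) + at(i + 1, j + 1, k) -
             at(i - 1, j - 1, k) - 2 * at(i, j - 1, k) - at(i + 1, j - 1, k)) / 8
      sy <- (at(i + 1, j - 1, k) + 2 * at(i + 1, j, k) + at(i + 1, j + 1, k) -
             at(i - 1, j - 1, k) - 2 * at(i - 1, j, k) - at(i - 1, j + 1, k)) / 8
      m <- sqrt(sx^2 + sy^2)
      if (m > bm) { bm <- m; gx[i, j] <- sx; gy[i, j] <- sy }
    }
    mag[i, j] <- bm
  }
  levels <- vector("list", max_level + 1)
  for (lv in 0:max_level) {
    nsub <- 2^lv
    rcut <- floor(seq(0, h, length.out = nsub + 1))
    ccut <- floor(seq(0, w, length.out = nsub + 1))
    hm <- matrix(0, nsub * nsub, bins)
    for (bi in seq_len(nsub)) for (bj in seq_len(nsub)) {
      hist <- numeric(bins)
      for (i in (rcut[bi] + 1):rcut[bi + 1]) for (j in (ccut[bj] + 1):ccut[bj + 1]) {
        th <- (atan2(gy[i, j], gx[i, j]) * 180 / pi) %% 180
        b <- min(floor(th / (180 / bins)) + 1, bins)
        hist[b] <- hist[b] + mag[i, j]
      }
      if (sum(hist) > 0) hist <- hist / sum(hist)
      hm[(bi - 1) * nsub + bj, ] <- hist
    }
    levels[[lv + 1]] <- hm
  }
  list(levels = levels, mean_mag = mean(mag))
}

# random point cloud whose exact hull volume is known by construction:
# vertices of a random parallelepiped (volume |det|) plus interior points
# sampled as convex combinations of the vertices
known_volume_cloud <- function(n_interior, seed) {
  set.seed(seed)
  repeat {
    B <- matrix(rnorm(9, sd = 10), 3, 3)
    if (abs(det(B)) > 50) break
  }
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1)) %*% t(B)
  wts <- matrix(rexp(n_interior * 8), n_interior, 8)
  wts <- wts / rowSums(wts)
  list(pts = rbind(corners, wts %*% corners), volume = abs(det(B)))
}

# points on an ellipse: centre (cx, cy), semi-axes (ra, rb), angle deg
ellipse_points <- function(n, cx, cy, ra, rb, angle_deg, noise = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  th <- angle_deg * pi / 180
  x0 <- ra * cos(t); y0 <- rb * sin(t)
  cbind(cx + x0 * cos(th) - y0 * sin(th) + rnorm(n, 0, noise),
        cy + x0 * sin(th) + y0 * cos(th) + rnorm(n, 0, noise))
}
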