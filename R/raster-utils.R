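# Internal raster helpers. Masks are logical/integer matrices indexed
# [row = y, col = x], origin top-left, 8-connected regions.

# Integer offsets covering a disc of radius r (pixels), as a 2-column
# matrix (dy, dx) relative to the centre pixel.
disc_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# Stamp discs of radius r[i] at integer centres (cy[i], cx[i]) into `mat`,
# setting stamped pixels to `value`. Returns the modified matrix.
stamp_discs <- function(mat, cy, cx, r, value = TRUE) {
  h <- nrow(mat); w <- ncol(mat)
  if (length(r) == 1) r <- rep(r, length(cy))
  for (k in seq_along(cy)) {
    off <- disc_offsets(r[k])
    yy <- cy[k] + off[, 1]; xx <- cx[k] + off[, 2]
    keep <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    mat[cbind(yy[keep], xx[keep])] <- value
  }
  mat
}

# Stamp discs at continuous (sub-pixel) centres: pixel centres within
# r[i] of (cy[i], cx[i]) are set to `value`. Unbiased rasterization
# (no centre rounding), used for track clearing.
stamp_discs_cont <- function(mat, cy, cx, r, value = TRUE) {
  h <- nrow(mat); w <- ncol(mat)
  if (length(r) == 1) r <- rep(r, length(cy))
  for (k in seq_along(cy)) {
    ys <- max(1, floor(cy[k] - r[k])):min(h, ceiling(cy[k] + r[k]))
    xs <- max(1, floor(cx[k] - r[k])):min(w, ceiling(cx[k] + r[k]))
    if (length(ys) == 0 || length(xs) == 0) next
    inside <- outer((ys - cy[k])^2, (xs - cx[k])^2, "+") <= r[k]^2
    if (any(inside)) {
      sub <- mat[ys, xs, drop = FALSE]
      sub[inside] <- value
      mat[ys, xs] <- sub
    }
  }
  mat
}

# Densify a polyline (t, x, y in pixel units) so consecutive points are at
# most `step` px apart. Returns matrix with columns x, y.
densify_path <- function(x, y, step = 0.5) {
  if (length(x) == 1) return(cbind(x = x, y = y))
  segs <- lapply(seq_len(length(x) - 1), function(i) {
    d <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    n <- max(1L, ceiling(d / step))
    s <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    cbind(x = x[i] + s * (x[i + 1] - x[i]),
          y = y[i] + s * (y[i + 1] - y[i]))
  })
  rbind(do.call(rbind, segs), cbind(x = x[length(x)], y = y[length(y)]))
}

# Perimeter of the outer boundary of a single connected mask, from the
# 8-connected boundary chain with the Vossepoel-Smeulders corner
# correction (accurate to ~1% for smooth convex shapes):
#   P = 0.980 * n_axial + 1.406 * n_diagonal - 0.091 * n_corner.
mask_perimeter <- function(mask) {
  cont <- EBImage::ocontour(EBImage::Image(t(mask * 1)))
  if (length(cont) == 0) return(0)
  # longest contour = outer boundary
  oc <- cont[[which.max(vapply(cont, nrow, integer(1)))]]
  n <- nrow(oc)
  if (n == 1) return(4 * 0.980)  # lone pixel: unit-square-ish boundary
  nxt <- c(2:n, 1)
  dx <- oc[nxt, 1] - oc[, 1]
  dy <- oc[nxt, 2] - oc[, 2]
  dlen <- pmax(abs(dx), abs(dy))
  # ocontour steps are single 8-neighbour moves; guard anyway
  diag_step <- abs(dx) == abs(dy) & dlen > 0
  n_diag <- sum(dlen[diag_step])
  n_axial <- sum(dlen[!diag_step])
  code <- atan2(dy, dx)
  n_corner <- sum(code != c(code[-1], code[1]))
  max(0.980 * n_axial + 1.406 * n_diag - 0.091 * n_corner, 1)
}

# Convex hull area of a pixel mask, computed over the 4 corners of every
# pixel so the hull always contains the full pixel squares (guarantees
# hull area >= pixel count).
mask_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  px <- c(x - 0.5, x + 0.5, x + 0.5, x - 0.5)
  py <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  nh <- length(h)
  j <- c(2:nh, 1)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

# Ellipse-equivalent axes from second central moments of pixel coordinates
# (with the 1/12 per-pixel variance term). Returns c(major, minor) = full
# axis lengths, major >= minor > 0.
mask_axes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  n <- length(x)
  cxx <- sum((x - mean(x))^2) / n + 1 / 12
  cyy <- sum((y - mean(y))^2) / n + 1 / 12
  cxy <- sum((x - mean(x)) * (y - mean(y))) / n
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  c(major = 4 * sqrt(max(ev[1], 0)), minor = 4 * sqrt(max(ev[2], 1e-12)))
}

# Label matrix -> list of logical masks (named by label id).
label_masks <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  setNames(lapply(ids, function(i) labels == i), ids)
}

# Centroids (y, x) of each label id in a label matrix.
label_centroids <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  out <- t(vapply(ids, function(i) {
    idx <- which(labels == i, arr.ind = TRUE)
    c(y = mean(idx[, 1]), x = mean(idx[, 2]), area = nrow(idx))
  }, c(y = 0, x = 0, area = 0)))
  data.frame(id = ids, y = out[, "y"], x = out[, "x"], area = out[, "area"])
}
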