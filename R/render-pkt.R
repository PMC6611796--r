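#' Render a synthetic phagokinetic-track montage
#'
#' Draws a bead-lawn whole-well montage: dark latex-bead puncta on a bright
#' background, with bead-free migratory tracks cleared along each supplied
#' cell path and a dark cell body rendered at every path end. The montage
#' corresponds to a 6 x 6 tile acquisition by default; a ground-truth label
#' mask assigns each track's cleared pixels a unique id.
#'
#' @param paths List of path data.frames (`t`, `x`, `y` in µm, as from
#'   [simulate_prw_path()]); each path is shifted by its origin from
#'   `origins` before scaling to pixels.
#' @param params A [motility_params()] object (or list of one per path)
#'   supplying `track_width` (µm) and `protrusiveness`.
#' @param image_shape Height, width of the montage in px.
#' @param um_per_px Pixel size, µm (default 0.65, a x10 objective).
#' @param bead_density Beads per µm² (> 0).
#' @param bead_radius_px Bead radius in px.
#' @param noise_sd Gaussian intensity noise SD added to the image.
#' @param tiles Tiling of the montage (rows, cols); metadata only.
#' @param origins Optional 2-column matrix (x, y in µm) of path start
#'   offsets; defaults to spreading path origins over the field.
#' @param cell_radius_px Semi-major radius of the rendered cell body (px).
#' @param seed Integer seed.
#'
#' @return A list with `image` (matrix in `[0, 1]`, `[y, x]` indexing),
#'   `labels` (integer matrix, one id per track), `collisions` (ids of
#'   tracks whose cleared areas overlap another track), and `info`
#'   (pixel scale, tiling, `n_images`).
#' @examples
#' p <- simulate_prw_path(motility_params(speed = 1, persistence_time = 1e6),
#'                        n_steps = 20, dt = 10, seed = 1)
#' m <- render_pkt_montage(list(p), motility_params(track_width = 15),
#'                         image_shape = c(300, 300), seed = 1)
#' range(m$labels)
#' @export
render_pkt_montage <- function(paths, params = motility_params(),
                               image_shape = c(600, 600),
                               um_per_px = 0.65,
                               bead_density = 0.25,
                               bead_radius_px = 1.5,
                               noise_sd = 0.01,
                               tiles = c(6, 6),
                               origins = NULL,
                               cell_radius_px = 9,
                               seed = NULL) {
  stop_if_not(bead_density > 0, "`bead_density` must be > 0 (beads/um^2)")
  h <- image_shape[1]; w <- image_shape[2]
  n_paths <- length(paths)
  if (inherits(params, "motility_params")) {
    params <- rep(list(params), max(1, n_paths))
  }
  bg <- 0.85; bead_val <- 0.25; cell_val <- 0.05

  with_seed(seed, {
    img <- matrix(bg, h, w)
    # bead lawn: Poisson-sampled dark puncta
    n_beads <- rpois(1, bead_density * h * w * um_per_px^2)
    by <- sample.int(h, n_beads, replace = TRUE)
    bx <- sample.int(w, n_beads, replace = TRUE)
    img <- stamp_discs(img, by, bx, bead_radius_px, bead_val)

    labels <- matrix(0L, h, w)
    collisions <- integer(0)
    if (n_paths > 0) {
      if (is.null(origins)) origins <- default_origins(n_paths, h, w, um_per_px)
      for (i in seq_len(n_paths)) {
        pp <- paths[[i]]
        px <- (pp$x + origins[i, 1]) / um_per_px
        py <- (pp$y + origins[i, 2]) / um_per_px
        stop_if_not(all(px >= 1 & px <= w & py >= 1 & py <= h),
                    sprintf("path %d leaves the field after scaling", i))
        half_w <- params[[i]]$track_width / 2 / um_per_px
        dense <- densify_path(px, py, step = 0.5)
        radii <- rep(half_w, nrow(dense))
        track <- matrix(FALSE, h, w)
        track <- stamp_discs_cont(track, dense[, "y"], dense[, "x"], radii)
        prot <- params[[i]]$protrusiveness
        if (prot > 0 && nrow(dense) > 2) {
          # boundary protrusions: small lobes stamped on the track edge
          # (one per ~20 px of path per unit protrusiveness)
          nd <- nrow(dense)
          n_bump <- max(1L, round(prot * nd * 0.5 / 20))
          at <- sample(2:(nd - 1), n_bump, replace = TRUE)
          side <- sample(c(-1, 1), n_bump, replace = TRUE)
          tx <- dense[at + 1, "x"] - dense[at - 1, "x"]
          ty <- dense[at + 1, "y"] - dense[at - 1, "y"]
          nrm <- sqrt(tx^2 + ty^2)
          bx <- dense[at, "x"] - side * ty / nrm * half_w
          by <- dense[at, "y"] + side * tx / nrm * half_w
          track <- stamp_discs_cont(track, by, bx,
                                    rep(0.4 * half_w, n_bump))
        }
        hit <- track & labels > 0
        if (any(hit)) {
          collisions <- union(collisions,
                              c(i, unique(labels[hit])))
        }
        img[track] <- bg            # cleared: beads removed
        labels[track] <- i
        # cell body at the path end, oriented along the final heading
        img <- draw_cell_body(img, px[length(px)], py[length(py)],
                              heading_of(px, py), cell_radius_px, cell_val)
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, labels = labels, collisions = sort(collisions),
         info = list(um_per_px = um_per_px, tiles = tiles,
                     n_images = prod(tiles)))
  })
}

# Spread path origins over the field interior on a jitter-free grid.
default_origins <- function(n, h, w, um_per_px) {
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  gx <- seq(0.2, 0.8, length.out = nc) * w * um_per_px
  gy <- seq(0.2, 0.8, length.out = nr) * h * um_per_px
  g <- expand.grid(x = gx, y = gy)
  as.matrix(g[seq_len(n), , drop = FALSE])
}

heading_of <- function(px, py) {
  n <- length(px)
  if (n < 2) return(0)
  atan2(py[n] - py[n - 1], px[n] - px[n - 1])
}

# Filled ellipse (semi-axes a, 0.7a) at centre (cx, cy), rotated by theta.
draw_cell_body <- function(img, cx, cy, theta, a, value) {
  b <- 0.7 * a
  ri <- ceiling(a)
  ys <- max(1, px_index(cy) - ri):min(nrow(img), px_index(cy) + ri)
  xs <- max(1, px_index(cx) - ri):min(ncol(img), px_index(cx) + ri)
  g <- expand.grid(y = ys, x = xs)
  u <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  v <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img[cbind(g$y[inside], g$x[inside])] <- value
  img
}
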