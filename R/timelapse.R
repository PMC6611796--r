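#' Generate a synthetic GFP time-lapse movie with ground truth
#'
#' Renders moving cells as Gaussian blobs following persistent-random-walk
#' paths, sampled at the live-assay acquisition settings: one frame every
#' 12 min for 12 h (61 frames) by default. Cells are placed on a jittered
#' grid; paths that would leave the field are reflected at a safety margin
#' so the rendered positions always match the recorded ground truth.
#'
#' @param n_cells Number of cells (>= 0).
#' @param params A [motility_params()] object, or list of one per cell.
#' @param n_frames Number of frames (>= 2; default 61).
#' @param dt Frame interval in min (default 12).
#' @param image_shape Height, width in px.
#' @param um_per_px Pixel size in µm (default 0.33, a x20 objective).
#' @param cell_radius_um Cell radius in µm (blob sigma is half the
#'   radius); must be well below the image extent.
#' @param noise_sd Gaussian intensity noise SD.
#' @param seed Integer seed.
#' @return List with `stack` (array `[y, x, frame]`, intensities in
#'   `[0, 1]`), `ground_truth` (data.frame `cell_id`, `frame`, `t`, `x`,
#'   `y`, in min/µm) and `info` (dt, scale, radius).
#' @examples
#' mv <- generate_timelapse(n_cells = 2, n_frames = 5,
#'                          image_shape = c(120, 120), um_per_px = 1,
#'                          cell_radius_um = 10, seed = 1)
#' dim(mv$stack)
#' @export
generate_timelapse <- function(n_cells,
                               params = motility_params(speed = 0.4,
                                                        persistence_time = 30,
                                                        track_width = 20),
                               n_frames = 61L, dt = 12,
                               image_shape = c(400, 400),
                               um_per_px = 0.33,
                               cell_radius_um = 12,
                               noise_sd = 0.01,
                               seed = NULL) {
  stop_if_not(n_frames >= 2, "`n_frames` must be >= 2")
  stop_if_not(n_cells >= 0, "`n_cells` must be >= 0")
  h <- image_shape[1]; w <- image_shape[2]
  r_px <- cell_radius_um / um_per_px
  stop_if_not(2 * r_px < min(h, w),
              "cell radius must be smaller than the image extent")
  if (inherits(params, "motility_params")) {
    params <- rep(list(params), max(1, n_cells))
  }
  sigma <- r_px / 2

  with_seed(seed, {
    margin <- 1.2 * r_px
    # jittered grid of start positions, in um
    nc <- max(1, ceiling(sqrt(n_cells)))
    nr <- max(1, ceiling(n_cells / nc))
    gx <- seq(margin, w - margin, length.out = nc + 2)[-c(1, nc + 2)]
    gy <- seq(margin, h - margin, length.out = nr + 2)[-c(1, nr + 2)]
    grid <- expand.grid(x = gx, y = gy)[seq_len(max(0, n_cells)), ,
                                        drop = FALSE]
    gt <- list()
    pos <- vector("list", max(0, n_cells))
    for (i in seq_len(n_cells)) {
      path <- simulate_prw_path(params[[i]], n_steps = n_frames - 1, dt = dt,
                                seed = split_seed(seed %||% 0L, 7L, i))
      px <- grid$x[i] + path$x / um_per_px
      py <- grid$y[i] + path$y / um_per_px
      px <- reflect_into(px, margin, w - margin)
      py <- reflect_into(py, margin, h - margin)
      pos[[i]] <- cbind(x = px, y = py)
      gt[[i]] <- data.frame(cell_id = i, frame = seq_len(n_frames),
                            t = path$t, x = px * um_per_px,
                            y = py * um_per_px)
    }
    stack <- array(0, dim = c(h, w, n_frames))
    for (f in seq_len(n_frames)) {
      frame <- matrix(0, h, w)
      for (i in seq_len(n_cells)) {
        frame <- add_gaussian_blob(frame, pos[[i]][f, "x"], pos[[i]][f, "y"],
                                   sigma)
      }
      if (noise_sd > 0) frame <- frame + matrix(rnorm(h * w, 0, noise_sd), h, w)
      stack[, , f] <- pmin(pmax(frame, 0), 1)
    }
    list(stack = stack,
         ground_truth = if (length(gt)) do.call(rbind, gt) else
           data.frame(cell_id = integer(0), frame = integer(0),
                      t = numeric(0), x = numeric(0), y = numeric(0)),
         info = list(dt = dt, um_per_px = um_per_px, n_frames = n_frames,
                     cell_radius_um = cell_radius_um))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflect coordinates into [lo, hi] (billiard map); isometric except at
# fold points, so rendered positions stay in frame.
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

add_gaussian_blob <- function(frame, cx, cy, sigma) {
  ri <- ceiling(4 * sigma)
  ys <- max(1, px_index(cy) - ri):min(nrow(frame), px_index(cy) + ri)
  xs <- max(1, px_index(cx) - ri):min(ncol(frame), px_index(cx) + ri)
  g <- exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sigma^2))
  frame[ys, xs] <- pmax(frame[ys, xs], g)
  frame
}

#' Write / read a time-lapse stack as multi-page TIFF
#'
#' @param stack Array `[y, x, frame]` with values in `[0, 1]`.
#' @param path File path.
#' @return `read_image_stack()` returns the array.
#' @export
write_image_stack <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}
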