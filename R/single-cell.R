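#' Segment cells in one time-lapse frame
#'
#' Threshold-based segmentation of fluorescent (GFP) cells with a
#' distance-map watershed to split touching blobs: pixels above
#' `threshold` (an absolute intensity, or `"auto"` for half the frame
#' maximum) form the foreground, which is labeled and split where the
#' distance transform has separate peaks. Deterministic for a fixed frame.
#'
#' @param frame Single-channel image matrix (`[y, x]`, intensities in
#'   `[0, 1]`).
#' @param threshold Absolute intensity cut, or `"auto"`.
#' @param min_area Minimum cell area in px².
#' @param blank_floor Frames whose maximum is below this are treated as
#'   blank (zero cells).
#' @return List with `labels` (integer matrix) and `centroids`
#'   (data.frame `id`, `y`, `x`, `area`).
#' @export
segment_cells_frame <- function(frame, threshold = "auto", min_area = 30,
                                blank_floor = 0.1) {
  stop_if_not(is.matrix(frame), "`frame` must be a single-channel matrix")
  if (max(frame) < blank_floor) {
    return(list(labels = matrix(0L, nrow(frame), ncol(frame)),
                centroids = data.frame(id = integer(0), y = numeric(0),
                                       x = numeric(0), area = numeric(0))))
  }
  thr <- if (identical(threshold, "auto")) max(frame) / 2 else threshold
  mask <- frame > thr
  dm <- EBImage::distmap(t(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = 1)
  labels <- t(as.matrix(lab))
  # drop specks and relabel consecutively
  keep <- label_centroids(labels)
  keep <- keep[keep$area >= min_area, , drop = FALSE]
  new <- matrix(0L, nrow(labels), ncol(labels))
  for (j in seq_len(nrow(keep))) new[labels == keep$id[j]] <- j
  list(labels = new, centroids = label_centroids(new))
}

#' Link cell masks of consecutive frames by pixel overlap
#'
#' Greedy one-to-one matching of label masks from frame t to frame t+1 by
#' decreasing pixel-overlap count; ties are broken by lowest label pair.
#' Pairs overlapping fewer than `min_overlap_px` pixels stay unmatched:
#' unmatched next-frame masks start new tracks and unmatched current masks
#' terminate theirs.
#'
#' @param labels_a,labels_b Integer label matrices of consecutive frames.
#' @param min_overlap_px Minimum overlap (default 1: any overlap links).
#' @return Data.frame with `from`, `to`, `overlap` (one row per match).
#' @export
link_by_overlap <- function(labels_a, labels_b, min_overlap_px = 1) {
  if (is.logical(labels_a)) storage.mode(labels_a) <- "integer"
  if (is.logical(labels_b)) storage.mode(labels_b) <- "integer"
  both <- labels_a > 0 & labels_b > 0
  if (!any(both)) {
    return(data.frame(from = integer(0), to = integer(0),
                      overlap = integer(0)))
  }
  ov <- as.data.frame(table(from = labels_a[both], to = labels_b[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq >= min_overlap_px, , drop = FALSE]
  ov$from <- as.integer(ov$from); ov$to <- as.integer(ov$to)
  ov <- ov[order(-ov$Freq, ov$from, ov$to), , drop = FALSE]
  used_a <- integer(0); used_b <- integer(0); keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (!(ov$from[i] %in% used_a) && !(ov$to[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, ov$from[i]); used_b <- c(used_b, ov$to[i])
    }
  }
  out <- ov[keep, , drop = FALSE]
  data.frame(from = out$from, to = out$to, overlap = out$Freq)
}

#' Build trajectories from frame-to-frame correspondences
#'
#' Chains per-frame detections into cell trajectories and applies the
#' minimum-duration filter: only cells tracked for at least
#' `min_duration` minutes (2 h at the default 12-min interval, i.e. >= 11
#' samples) are kept. Gaps are not bridged: a missed detection terminates
#' the track and any re-detection starts a new one.
#'
#' @param detections List of per-frame detections (each with `centroids`
#'   as from [segment_cells_frame()]).
#' @param links List of length `length(detections) - 1` of link tables
#'   from [link_by_overlap()].
#' @param dt Sampling interval in min (default 12).
#' @param min_duration Minimum tracked duration in min (default 120,
#'   boundary inclusive).
#' @param um_per_px Pixel size (µm) used to convert centroids to µm.
#' @return List of trajectory data.frames (`cell_id`, `frame`, `t`, `x`,
#'   `y`; µm and min), class `trajectory` each.
#' @export
build_trajectories <- function(detections, links, dt = 12,
                               min_duration = 120, um_per_px = 1) {
  n_frames <- length(detections)
  stop_if_not(length(links) == n_frames - 1,
              "need one link table per consecutive frame pair")
  # active[label in current frame] -> trajectory index
  trajs <- list(); active <- list()
  new_traj <- function(frame, id) {
    c0 <- detections[[frame]]$centroids
    r <- c0[c0$id == id, ]
    data.frame(frame = frame, t = (frame - 1) * dt,
               x = r$x * um_per_px, y = r$y * um_per_px)
  }
  cent0 <- detections[[1]]$centroids
  for (id in cent0$id) {
    trajs[[length(trajs) + 1L]] <- new_traj(1, id)
    active[[as.character(id)]] <- length(trajs)
  }
  for (f in seq_len(n_frames - 1)) {
    lk <- links[[f]]
    nxt <- list()
    cents <- detections[[f + 1]]$centroids
    for (id in cents$id) {
      row <- lk[lk$to == id, , drop = FALSE]
      prev <- if (nrow(row) == 1) active[[as.character(row$from)]] else NULL
      r <- cents[cents$id == id, ]
      pt <- data.frame(frame = f + 1, t = f * dt,
                       x = r$x * um_per_px, y = r$y * um_per_px)
      if (!is.null(prev)) {
        trajs[[prev]] <- rbind(trajs[[prev]], pt)
        nxt[[as.character(id)]] <- prev
      } else {
        trajs[[length(trajs) + 1L]] <- pt
        nxt[[as.character(id)]] <- length(trajs)
      }
    }
    active <- nxt
  }
  out <- list()
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    if (nrow(tr) < 2) next
    if (tr$t[nrow(tr)] - tr$t[1] < min_duration) next
    tr <- cbind(cell_id = length(out) + 1L, tr)
    class(tr) <- c("trajectory", "data.frame")
    out[[length(out) + 1L]] <- tr
  }
  out
}

#' Track a whole time-lapse stack
#'
#' Convenience composition of [segment_cells_frame()], [link_by_overlap()]
#' and [build_trajectories()].
#'
#' @param stack 3-D array `[y, x, frame]` or list of frame matrices.
#' @param dt,min_duration,um_per_px As in [build_trajectories()].
#' @param min_overlap_px As in [link_by_overlap()].
#' @param ... Passed to [segment_cells_frame()].
#' @return List of `trajectory` data.frames.
#' @export
track_movie <- function(stack, dt = 12, min_duration = 120, um_per_px = 1,
                        min_overlap_px = 1, ...) {
  frames <- if (is.array(stack) && length(dim(stack)) == 3) {
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  } else stack
  stop_if_not(length(frames) >= 2, "need at least 2 frames")
  det <- lapply(frames, segment_cells_frame, ...)
  links <- lapply(seq_len(length(det) - 1), function(f) {
    link_by_overlap(det[[f]]$labels, det[[f + 1]]$labels,
                    min_overlap_px = min_overlap_px)
  })
  build_trajectories(det, links, dt = dt, min_duration = min_duration,
                     um_per_px = um_per_px)
}

#' Per-trajectory migration statistics
#'
#' Speed is the path length divided by the tracked duration (mean
#' frame-to-frame displacement per minute), displacement the straight-line
#' start-to-end distance, and the directionality ratio their quotient
#' (displacement / path length, in `[0, 1]`; 0 by convention for a
#' stationary cell).
#'
#' @param trajectory A `trajectory` data.frame (columns `t`, `x`, `y`;
#'   >= 2 samples).
#' @return One-row data.frame: `cell_id`, `n_samples`, `duration` (min),
#'   `speed` (µm/min), `displacement` (µm), `path_length` (µm),
#'   `directionality`.
#' @export
trajectory_stats <- function(trajectory) {
  stop_if_not(nrow(trajectory) >= 2, "trajectory needs at least 2 samples")
  n <- nrow(trajectory)
  steps <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)
  dur <- trajectory$t[n] - trajectory$t[1]
  path <- sum(steps)
  disp <- sqrt((trajectory$x[n] - trajectory$x[1])^2 +
                 (trajectory$y[n] - trajectory$y[1])^2)
  data.frame(cell_id = if ("cell_id" %in% names(trajectory))
               trajectory$cell_id[1] else NA_integer_,
             n_samples = n, duration = dur,
             speed = path / dur, displacement = disp, path_length = path,
             directionality = if (path > 0) disp / path else 0)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise rank-based z statistics on the pooled ranks, with the standard
#' tie correction, and Bonferroni adjustment over all pairwise
#' comparisons (Dunn's classical form).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character of group membership.
#' @return Data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value` (two-sided), `p_adjusted`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  gl <- levels(groups)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  pairs <- utils::combn(gl, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out
}

#' Binomial order-statistic confidence interval for the median
#'
#' @param x Numeric vector.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `median`, `lower`, `upper`.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  alpha <- 1 - conf
  lo <- qbinom(alpha / 2, n, 0.5)
  hi <- n + 1 - lo
  c(median = median(x),
    lower = x[max(1, lo)], upper = x[min(n, hi)])
}

#' Compare knockdown speeds to both density-matched controls
#'
#' Implements the dual-control significance contract of the live
#' migration assay: a Kruskal-Wallis test across knockdown, low-density
#' control and high-density control, followed by Dunn's pairwise post test
#' (Bonferroni over the three pairs). The knockdown is called significant
#' only when it rejects against *both* controls at level `alpha`; the
#' effect direction is the sign of its median difference from the pooled
#' controls. Per-group medians with 95% CIs are reported.
#'
#' @param knockdown,control_low,control_high Numeric speed vectors
#'   (µm/min), at least `min_n` cells each.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum group size (default 5); smaller groups give an
#'   inconclusive verdict.
#' @return List with `verdict` (`"significant"`, `"not_significant"` or
#'   `"inconclusive"`), `direction` (-1/0/1), `kruskal_p`, `dunn`
#'   (pairwise table), `medians` (per-group median and CI) and `reason`
#'   for inconclusive verdicts.
#' @export
compare_to_controls <- function(knockdown, control_low, control_high,
                                alpha = 0.05, min_n = 5) {
  sizes <- c(knockdown = length(knockdown), control_low = length(control_low),
             control_high = length(control_high))
  meds <- rbind(knockdown = median_ci(knockdown),
                control_low = median_ci(control_low),
                control_high = median_ci(control_high))
  if (any(sizes < min_n)) {
    return(list(verdict = "inconclusive", direction = NA_integer_,
                kruskal_p = NA_real_, dunn = NULL, medians = meds,
                reason = sprintf("group(s) below minimum size %d: %s",
                                 min_n,
                                 paste(names(sizes)[sizes < min_n],
                                       collapse = ", "))))
  }
  values <- c(knockdown, control_low, control_high)
  groups <- rep(c("knockdown", "control_low", "control_high"), sizes)
  kw <- kruskal.test(values, factor(groups))
  dn <- dunn_test(values, groups)
  pick <- function(a, b) {
    dn$p_adjusted[(dn$group1 == a & dn$group2 == b) |
                    (dn$group1 == b & dn$group2 == a)]
  }
  sig <- pick("knockdown", "control_low") < alpha &&
    pick("knockdown", "control_high") < alpha
  dir <- sign(median(knockdown) - median(c(control_low, control_high)))
  list(verdict = if (sig) "significant" else "not_significant",
       direction = as.integer(dir),
       kruskal_p = kw$p.value, dunn = dn, medians = meds, reason = NULL)
}
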