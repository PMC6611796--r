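render_blob_frame <- function(h, w, centers, sigma = 5) {
  f <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    ys <- seq_len(h); xs <- seq_len(w)
    f <- pmax(f, exp(-outer((ys - centers[i, 2])^2,
                            (xs - centers[i, 1])^2, "+") / (2 * sigma^2)))
  }
  f
}

test_that("single blobs are segmented with sub-pixel-accurate centroids", {
  f <- render_blob_frame(100, 120, cbind(60.4, 45.7))
  s <- segment_cells_frame(f)
  expect_equal(nrow(s$centroids), 1)
  expect_lt(abs(s$centroids$x - 60.4), 1)
  expect_lt(abs(s$centroids$y - 45.7), 1)

  two <- render_blob_frame(100, 120, rbind(c(30, 50), c(80, 50)))
  s2 <- segment_cells_frame(two)
  expect_equal(nrow(s2$centroids), 2)

  blank <- segment_cells_frame(matrix(0, 50, 50))
  expect_equal(nrow(blank$centroids), 0)
})

test_that("overlap linking is greedy, one-to-one and threshold-respecting", {
  lab <- matrix(0L, 50, 50)
  lab[10:20, 10:20] <- 1L
  lab[30:40, 30:40] <- 2L
  # identical masks: identity matching
  id <- link_by_overlap(lab, lab)
  expect_equal(id$from, id$to)

  # small translation keeps the link, large translation breaks it
  near <- matrix(0L, 50, 50); near[13:23, 12:22] <- 1L
  expect_equal(nrow(link_by_overlap(lab == 1, near)), 1)
  far <- matrix(0L, 50, 50); far[35:45, 35:45] <- 1L
  expect_equal(nrow(link_by_overlap((lab == 1) * 1L, far)), 0)

  # min_overlap_px above the actual overlap breaks the link
  shift <- matrix(0L, 50, 50); shift[20:30, 20:30] <- 1L
  ov <- link_by_overlap((lab == 1) * 1L, shift)
  expect_equal(ov$overlap, 1)
  expect_equal(nrow(link_by_overlap((lab == 1) * 1L, shift,
                                    min_overlap_px = 2)), 0)
})

test_that("trajectory building applies the 2-hour minimum inclusively", {
  mk_det <- function(n_frames, present) {
    lapply(seq_len(n_frames), function(f) {
      if (f %in% present) {
        lab <- matrix(0L, 30, 30); lab[10:15, 10:15] <- 1L
        list(labels = lab,
             centroids = data.frame(id = 1L, y = 12.5, x = 12.5, area = 36))
      } else {
        list(labels = matrix(0L, 30, 30),
             centroids = data.frame(id = integer(0), y = numeric(0),
                                    x = numeric(0), area = numeric(0)))
      }
    })
  }
  chain <- function(det) {
    lapply(seq_len(length(det) - 1), function(f) {
      link_by_overlap(det[[f]]$labels, det[[f + 1]]$labels)
    })
  }
  # 11 samples at dt = 12 -> 120 min: kept at the boundary
  d11 <- mk_det(11, 1:11)
  t11 <- build_trajectories(d11, chain(d11))
  expect_length(t11, 1)
  expect_equal(nrow(t11[[1]]), 11)
  expect_equal(t11[[1]]$t[11] - t11[[1]]$t[1], 120)

  # 9 samples -> discarded
  d9 <- mk_det(9, 1:9)
  expect_length(build_trajectories(d9, chain(d9)), 0)

  # a gap splits the chain; both fragments are too short
  d_gap <- mk_det(21, c(1:10, 12:21))
  expect_length(build_trajectories(d_gap, chain(d_gap)), 0)

  # empty input
  d0 <- mk_det(3, integer(0))
  expect_length(build_trajectories(d0, chain(d0)), 0)
})

test_that("duration filtering matches a brute-force scan over chain lengths", {
  set.seed(12)
  for (rep in 1:5) {
    n_frames <- 30
    present <- sort(sample(seq_len(n_frames), 22))
    det <- lapply(seq_len(n_frames), function(f) {
      if (f %in% present) {
        lab <- matrix(0L, 20, 20); lab[8:12, 8:12] <- 1L
        list(labels = lab, centroids = data.frame(id = 1L, y = 10, x = 10,
                                                  area = 25))
      } else {
        list(labels = matrix(0L, 20, 20),
             centroids = data.frame(id = integer(0), y = numeric(0),
                                    x = numeric(0), area = numeric(0)))
      }
    })
    links <- lapply(seq_len(n_frames - 1), function(f) {
      link_by_overlap(det[[f]]$labels, det[[f + 1]]$labels)
    })
    got <- length(build_trajectories(det, links, dt = 12,
                                     min_duration = 120))
    # oracle: run lengths of consecutive presence
    runs <- rle(seq_len(n_frames) %in% present)
    want <- sum(runs$lengths[runs$values] >= 11)
    expect_equal(got, want)
  }
})

test_that("trajectory statistics match closed-form arithmetic", {
  straight <- data.frame(cell_id = 1, frame = 1:11, t = seq(0, 120, by = 12),
                         x = seq(0, 10, by = 1), y = 0)
  s <- trajectory_stats(straight)
  expect_equal(s$speed, 1 / 12, tolerance = 1e-9)
  expect_equal(s$directionality, 1, tolerance = 1e-9)
  expect_equal(s$displacement, 10)

  still <- transform(straight, x = 0)
  s0 <- trajectory_stats(still)
  expect_equal(s0$speed, 0)
  expect_equal(s0$directionality, 0)   # convention for zero path length

  expect_error(trajectory_stats(straight[1, ]), "2 samples")

  # path length always >= displacement on random walks
  set.seed(2)
  for (i in 1:10) {
    tr <- data.frame(t = seq(0, 120, by = 12), x = cumsum(rnorm(11)),
                     y = cumsum(rnorm(11)))
    st <- trajectory_stats(tr)
    expect_gte(st$path_length, st$displacement - 1e-12)
    expect_true(st$directionality >= 0 && st$directionality <= 1)
  }
})

test_that("PRW movies are tracked with correct identities and speeds", {
  mp <- motility_params(speed = 0.35, persistence_time = 5, track_width = 20)
  mv <- generate_timelapse(n_cells = 6, params = mp, n_frames = 31, dt = 12,
                           image_shape = c(300, 360), um_per_px = 1.5,
                           cell_radius_um = 10, noise_sd = 0.01, seed = 31)
  trs <- track_movie(mv$stack, dt = 12, um_per_px = 1.5)
  expect_length(trs, 6)
  gt <- split(mv$ground_truth, mv$ground_truth$cell_id)
  # match each trajectory to its ground-truth cell by mean distance
  matched <- vapply(trs, function(tr) {
    dists <- vapply(gt, function(g) {
      mean(sqrt((tr$x - g$x)^2 + (tr$y - g$y)^2))
    }, numeric(1))
    which.min(dists)
  }, numeric(1))
  expect_setequal(matched, 1:6)
  for (k in seq_along(trs)) {
    g <- gt[[matched[k]]]
    expect_lt(max(sqrt((trs[[k]]$x - g$x)^2 + (trs[[k]]$y - g$y)^2)), 3)
    est <- trajectory_stats(trs[[k]])$speed
    ref <- sum(sqrt(diff(g$x)^2 + diff(g$y)^2)) / (max(g$t) - min(g$t))
    expect_equal(est, ref, tolerance = 0.05)
  }
})

test_that("speed estimates are invariant under stack translation/rotation", {
  mp <- motility_params(speed = 0.35, persistence_time = 5, track_width = 20)
  mv <- generate_timelapse(n_cells = 2, params = mp, n_frames = 15, dt = 12,
                           image_shape = c(200, 200), um_per_px = 1.5,
                           cell_radius_um = 10, noise_sd = 0, seed = 9)
  base <- sort(vapply(track_movie(mv$stack, dt = 12, um_per_px = 1.5),
                      function(t) trajectory_stats(t)$speed, numeric(1)))
  # translate by whole pixels (circular shift keeps blobs in-frame here)
  shifted <- mv$stack[c(31:200, 1:30), , , drop = FALSE]
  sh <- sort(vapply(track_movie(shifted, dt = 12, um_per_px = 1.5),
                    function(t) trajectory_stats(t)$speed, numeric(1)))
  expect_equal(sh, base, tolerance = 1e-6)
  # rotate 90 degrees
  rot <- aperm(mv$stack, c(2, 1, 3))
  ro <- sort(vapply(track_movie(rot, dt = 12, um_per_px = 1.5),
                    function(t) trajectory_stats(t)$speed, numeric(1)))
  expect_equal(ro, base, tolerance = 1e-6)
})

test_that("Dunn z-statistics match the comparison-counting oracle", {
  set.seed(5)
  for (rep in 1:8) {
    vals <- sample(1:6, 12, replace = TRUE)   # heavy ties
    grp <- rep(c("a", "b", "c"), each = 4)
    dn <- dunn_test(vals, grp)
    for (i in seq_len(nrow(dn))) {
      expect_equal(dn$z[i],
                   oracle_dunn_z(vals, grp, dn$group1[i], dn$group2[i]),
                   tolerance = 1e-12)
    }
    expect_equal(dn$p_adjusted, pmin(1, dn$p_value * 3))
  }
})

test_that("median CI covers the true median at the nominal rate", {
  set.seed(6)
  hits <- vapply(1:300, function(i) {
    x <- rnorm(25)
    ci <- median_ci(x)
    ci["lower"] <= 0 && 0 <= ci["upper"]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("dual-control comparison requires rejection against both controls", {
  set.seed(7)
  lo <- rnorm(60, 1, 0.2); hi <- rnorm(60, 1, 0.2)
  same <- rnorm(60, 1, 0.2)
  slow <- rnorm(60, 0.45, 0.1)
  r_null <- compare_to_controls(same, lo, hi)
  expect_equal(r_null$verdict, "not_significant")
  r_eff <- compare_to_controls(slow, lo, hi)
  expect_equal(r_eff$verdict, "significant")
  expect_equal(r_eff$direction, -1L)
  # knockdown differing from only one control is not called
  mid <- rnorm(200, 1, 0.2)
  hi2 <- rnorm(200, 1.6, 0.2)
  r_one <- compare_to_controls(mid, lo, hi2)
  expect_equal(r_one$verdict, "not_significant")

  small <- compare_to_controls(rnorm(3), lo, hi)
  expect_equal(small$verdict, "inconclusive")
  expect_match(small$reason, "knockdown")
})
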