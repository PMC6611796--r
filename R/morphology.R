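#' Generate a synthetic cell/nucleus morphology scene
#'
#' Renders label masks for cells of one of three archetypes — `"spread"`
#' (large disc), `"compact"` (small disc) or `"spiky"` (disc with radial
#' protrusions) — each with one nucleus inside its body, plus a
#' configurable fraction of orphan nuclei without a cell body (to exercise
#' the rejection rule).
#'
#' @param n_cells Number of nuclei placed (>= 0); `round(orphan_fraction *
#'   n_cells)` of them get no cell body.
#' @param archetype One of `"spread"`, `"compact"`, `"spiky"`.
#' @param n_spikes Number of radial protrusions for the spiky archetype.
#' @param orphan_fraction Fraction of nuclei without a cell body.
#' @param image_shape Height, width in px.
#' @param jitter_sd SD (px) of placement jitter; 0 gives a noise-free
#'   deterministic render.
#' @param size_jitter Log-scale SD of per-cell size variation.
#' @param seed Integer seed.
#' @return List with `cell_labels` and `nucleus_labels` (integer
#'   matrices; ids match between the two where a body exists) and
#'   `ground_truth` (data.frame `cell_id`, `archetype`, `has_cell_body`,
#'   `n_spikes`).
#' @export
generate_morphology_scene <- function(n_cells,
                                      archetype = c("spread", "compact",
                                                    "spiky"),
                                      n_spikes = 6,
                                      orphan_fraction = 0,
                                      image_shape = NULL,
                                      jitter_sd = 0,
                                      size_jitter = 0,
                                      seed = NULL) {
  archetype <- match.arg(archetype)
  stop_if_not(n_cells >= 0, "`n_cells` must be >= 0")
  stop_if_not(orphan_fraction >= 0 && orphan_fraction <= 1,
              "`orphan_fraction` must be in [0, 1]")
  body_r <- switch(archetype, spread = 32, compact = 16, spiky = 18)
  spike_len <- 16
  spacing <- 2 * (body_r + spike_len) + 20
  nc <- max(1, ceiling(sqrt(n_cells)))
  nr <- max(1, ceiling(n_cells / nc))
  if (is.null(image_shape)) {
    image_shape <- c(nr * spacing + 20, nc * spacing + 20)
  }
  h <- image_shape[1]; w <- image_shape[2]
  cells <- matrix(0L, h, w); nucs <- matrix(0L, h, w)
  n_orphan <- round(orphan_fraction * n_cells)
  gt <- data.frame(cell_id = seq_len(n_cells),
                   archetype = rep(archetype, n_cells),
                   has_cell_body = rep(TRUE, n_cells),
                   n_spikes = rep(if (archetype == "spiky") n_spikes else 0L,
                                  n_cells))
  if (n_cells == 0) {
    return(list(cell_labels = cells, nucleus_labels = nucs,
                ground_truth = gt))
  }
  gt$has_cell_body[seq_len(n_orphan) + (n_cells - n_orphan)] <- FALSE
  gt$n_spikes[!gt$has_cell_body] <- 0L

  with_seed(seed, {
    for (i in seq_len(n_cells)) {
      row <- ceiling(i / nc); col <- i - (row - 1) * nc
      cy <- 10 + (row - 0.5) * spacing + rnorm(1, 0, jitter_sd)
      cx <- 10 + (col - 0.5) * spacing + rnorm(1, 0, jitter_sd)
      scale_i <- exp(rnorm(1, 0, size_jitter))
      if (gt$has_cell_body[i]) {
        r_i <- body_r * scale_i
        cells <- stamp_discs(cells, px_index(cy), px_index(cx), r_i, i)
        if (archetype == "spiky") {
          for (k in seq_len(n_spikes)) {
            th <- 2 * pi * (k - 1) / n_spikes
            s <- seq(0, 1, length.out = 24)
            sy <- cy + sin(th) * (r_i - 3 + s * (spike_len + 3))
            sx <- cx + cos(th) * (r_i - 3 + s * (spike_len + 3))
            sr <- 4 * (1 - s) + 1.5   # tapered protrusion
            cells <- stamp_discs(cells, px_index(sy), px_index(sx), sr, i)
          }
        }
      }
      nucs <- stamp_discs(nucs, px_index(cy), px_index(cx), 7 * scale_i, i)
    }
    list(cell_labels = cells, nucleus_labels = nucs, ground_truth = gt)
  })
}

#' Measure single-cell morphology from label masks
#'
#' Per nucleus: cell area, perimeter, form factor `4πA/P²` (1 for a
#' disc), protrusion ("spike") count and nucleus area. Nuclei without an
#' enclosing cell body are flagged (`has_cell_body = FALSE`) for
#' downstream rejection. Spikes are detected as residuals of a
#' morphological opening: protrusions thinner than `width_max` px are
#' removed by the opening and counted when they protrude at least
#' `depth_min` px from the opened body.
#'
#' @param nucleus_labels,cell_labels Integer label matrices (as from
#'   [generate_morphology_scene()] or an external segmentation); matching
#'   is by nucleus-centroid location, not by id.
#' @param depth_min Minimum protrusion depth in px (default 5).
#' @param width_max Maximum protrusion width in px (default 30); the
#'   opening radius is `width_max / 2`.
#' @return Data.frame with one row per nucleus: `nucleus_id`, `cell_id`
#'   (0 if orphan), `has_cell_body`, `area`, `perimeter`, `form_factor`,
#'   `spike_count`, `nucleus_area`.
#' @export
measure_cell_morphology <- function(nucleus_labels, cell_labels,
                                    depth_min = 5, width_max = 30) {
  stop_if_not(all(dim(nucleus_labels) == dim(cell_labels)),
              "masks must be aligned (same dimensions)")
  nuc_ids <- setdiff(sort(unique(as.vector(nucleus_labels))), 0)
  if (length(nuc_ids) == 0) {
    return(data.frame(nucleus_id = integer(0), cell_id = integer(0),
                      has_cell_body = logical(0), area = numeric(0),
                      perimeter = numeric(0), form_factor = numeric(0),
                      spike_count = integer(0), nucleus_area = numeric(0)))
  }
  cents <- label_centroids(nucleus_labels)
  rows <- lapply(seq_along(nuc_ids), function(k) {
    nid <- nuc_ids[k]
    ci <- cents[cents$id == nid, ]
    cell_id <- cell_labels[px_index(ci$y), px_index(ci$x)]
    nuc_area <- sum(nucleus_labels == nid)
    if (cell_id == 0) {
      return(data.frame(nucleus_id = nid, cell_id = 0L,
                        has_cell_body = FALSE, area = NA_real_,
                        perimeter = NA_real_, form_factor = NA_real_,
                        spike_count = NA_integer_, nucleus_area = nuc_area))
    }
    mask <- cell_labels == cell_id
    per <- mask_perimeter(mask)
    area <- sum(mask)
    data.frame(nucleus_id = nid, cell_id = as.integer(cell_id),
               has_cell_body = TRUE, area = area, perimeter = per,
               form_factor = min(1, 4 * pi * area / per^2),
               spike_count = count_spikes(mask, depth_min, width_max),
               nucleus_area = nuc_area)
  })
  do.call(rbind, rows)
}

# Spike counting by opening-residual analysis.
count_spikes <- function(mask, depth_min = 5, width_max = 30) {
  r_open <- max(1, round(width_max / 2))
  brush <- EBImage::makeBrush(2 * r_open + 1, "disc")
  opened <- t(as.matrix(EBImage::opening(t(mask * 1), brush)))
  resid <- mask & !(opened > 0)
  if (!any(resid)) return(0L)
  # distance of every pixel to the opened body
  dist_to_body <- t(as.matrix(EBImage::distmap(t(1 - (opened > 0)))))
  lab <- t(as.matrix(EBImage::bwlabel(t(resid * 1))))
  ids <- setdiff(unique(as.vector(lab)), 0)
  n <- 0L
  for (i in ids) {
    if (max(dist_to_body[lab == i]) >= depth_min) n <- n + 1L
  }
  n
}

#' Filter out overcrowded images
#'
#' Images with more than `max_cells` cells are dropped before profiling.
#'
#' @param cell_counts Named (or plain) integer vector of per-image cell
#'   counts.
#' @param max_cells Threshold (default 150; an image with exactly 150
#'   cells is kept).
#' @return Logical vector: `TRUE` for retained images.
#' @export
filter_images <- function(cell_counts, max_cells = 150) {
  cell_counts <= max_cells
}

#' Mock-normalized knockdown morphology profile
#'
#' Per feature, the log2 fold change of the knockdown's single-cell median
#' over the pooled median of the plate's two mock control wells. Cells
#' without a cell body are rejected first. Zero medians are guarded by a
#' small positive floor.
#'
#' @param cells Data.frame of the knockdown's cell records (as from
#'   [measure_cell_morphology()]).
#' @param mock_cells Data.frame pooling the cells of >= 2 mock wells.
#' @param features Feature columns to profile.
#' @param n_mock_wells Number of mock wells pooled in `mock_cells`
#'   (must be >= 2).
#' @param floor Positive floor applied to both medians.
#' @return List with `log2fc` (named vector), `n_cells`, `n_mock_cells`.
#' @export
profile_knockdown <- function(cells, mock_cells,
                              features = c("area", "perimeter",
                                           "form_factor", "spike_count",
                                           "nucleus_area"),
                              n_mock_wells = 2, floor = 1e-6) {
  stop_if_not(n_mock_wells >= 2,
              "morphology normalization needs >= 2 mock wells per plate")
  keep <- function(df) df[df$has_cell_body, , drop = FALSE]
  cells <- keep(cells); mock_cells <- keep(mock_cells)
  fc <- vapply(features, function(f) {
    log2(max(median(cells[[f]]), floor) /
           max(median(mock_cells[[f]]), floor))
  }, numeric(1))
  list(log2fc = fc, n_cells = nrow(cells), n_mock_cells = nrow(mock_cells))
}

#' Cluster knockdown morphology profiles
#'
#' Agglomerative hierarchical clustering of log2 fold-change profiles with
#' Euclidean distance and complete linkage; labels are produced by cutting
#' the dendrogram at a requested number of clusters.
#'
#' @param profiles Numeric matrix (knockdowns in rows, features in
#'   columns), no missing values, >= 2 rows.
#' @param k Requested number of clusters (<= number of profiles).
#' @return List with `hclust` (the dendrogram object), `labels` (cluster
#'   assignment per row) and `merge_heights`.
#' @export
cluster_profiles <- function(profiles, k = 2) {
  profiles <- as.matrix(profiles)
  stop_if_not(nrow(profiles) >= 2, "need at least 2 profiles")
  stop_if_not(!anyNA(profiles), "profiles must not contain missing values")
  stop_if_not(k <= nrow(profiles),
              "cannot request more clusters than profiles")
  hc <- hclust(dist(profiles, method = "euclidean"), method = "complete")
  list(hclust = hc, labels = cutree(hc, k = k), merge_heights = hc$height)
}
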