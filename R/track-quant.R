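#' Segment migratory tracks in a PKT montage
#'
#' Finds bead-free regions in a bead-lawn montage. The dark bead texture is
#' made solid by a morphological closing whose radius exceeds the typical
#' bead spacing; the complement then isolates cleared (migrated) regions.
#' Speckle is removed by an opening, interior holes (the cell body) are
#' filled, and connected components below `min_area` px² are dropped.
#' Border-touching regions are flagged and excluded by default.
#'
#' @param montage Single-channel image matrix in `[0, 1]` (`[y, x]`).
#' @param dark_cutoff Intensity below which a pixel counts as bead/cell.
#' @param close_radius Closing radius (px); should exceed half the largest
#'   bead gap but stay below half the track width.
#' @param open_radius Opening radius (px) for speckle suppression.
#' @param min_area Minimum region area in px² (default 50).
#' @param include_border Keep border-touching regions (default `FALSE`).
#'
#' @return List with `labels` (integer matrix), `n` regions kept,
#'   `border_ids` (flagged border-touching ids, dropped unless
#'   `include_border`), and `qc_warning` (`TRUE` for blank or saturated
#'   input, which yields zero regions).
#' @export
segment_tracks <- function(montage, dark_cutoff = 0.5, close_radius = 6,
                           open_radius = 3, min_area = 50,
                           include_border = FALSE) {
  stop_if_not(is.matrix(montage), "`montage` must be a single-channel matrix")
  dark <- montage < dark_cutoff
  dark_frac <- mean(dark)
  if (dark_frac < 0.01 || dark_frac > 0.9) {
    # blank (no beads) or saturated-dark image: nothing quantifiable
    return(list(labels = matrix(0L, nrow(montage), ncol(montage)), n = 0L,
                border_ids = integer(0), qc_warning = TRUE))
  }
  brush_c <- EBImage::makeBrush(2 * close_radius + 1, "disc")
  brush_o <- EBImage::makeBrush(2 * open_radius + 1, "disc")
  dark_t <- t(dark * 1)                            # EBImage works in [x, y]
  # dark blobs surviving an opening are cell bodies, not beads: keep them
  # out of the lawn so a track's own cell does not punch a hole in it
  cells_t <- EBImage::opening(dark_t, brush_o)
  lawn <- EBImage::closing(dark_t * (1 - cells_t), brush_c)
  cand <- EBImage::opening(1 - lawn, brush_o)
  cand <- EBImage::fillHull(cand)
  lab <- EBImage::bwlabel(cand)
  labels <- t(as.matrix(lab))                       # back to [y, x]
  labels <- filter_regions(labels, min_area, include_border)
  list(labels = labels$labels, n = labels$n, border_ids = labels$border_ids,
       qc_warning = FALSE)
}

# Drop small regions, flag border-touching ones, relabel 1..n.
filter_regions <- function(labels, min_area, include_border) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  if (length(ids) == 0) {
    return(list(labels = labels, n = 0L, border_ids = integer(0)))
  }
  areas <- tabulate(labels[labels > 0], nbins = max(ids))
  keep <- ids[areas[ids] >= min_area]
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  border <- intersect(setdiff(border, 0), keep)
  if (!include_border) keep <- setdiff(keep, border)
  new <- matrix(0L, nrow(labels), ncol(labels))
  for (j in seq_along(keep)) new[labels == keep[j]] <- j
  list(labels = new, n = length(keep), border_ids = border)
}

#' Count cell bodies inside each track region
#'
#' Cell bodies are rendered/stained much darker than beads; they are found
#' as compact dark blobs surviving an opening larger than any bead, then
#' assigned to track regions by centroid. Tracks without a cell or with
#' more than one cell are later rejected by [accept_tracks()].
#'
#' @param montage Image matrix as in [segment_tracks()].
#' @param regions Result of [segment_tracks()] on the same image.
#' @param cell_cutoff Intensity below which a pixel can belong to a cell
#'   body (between the cell and bead intensities).
#' @param open_radius Opening radius (px), larger than a bead radius.
#' @param min_cell_area Minimum cell-body area (px²).
#'
#' @return Integer vector: cell count per region id `1..regions$n`.
#' @export
detect_cell_bodies <- function(montage, regions, cell_cutoff = 0.15,
                               open_radius = 3, min_cell_area = 40) {
  stop_if_not(is.matrix(montage), "`montage` must be a single-channel matrix")
  n <- regions$n
  counts <- integer(n)
  if (n == 0) return(counts)
  cellmask <- montage < cell_cutoff
  brush <- EBImage::makeBrush(2 * open_radius + 1, "disc")
  opened <- EBImage::opening(t(cellmask * 1), brush)
  lab <- t(as.matrix(EBImage::bwlabel(opened)))
  cents <- label_centroids(lab)
  cents <- cents[cents$area >= min_cell_area, , drop = FALSE]
  # a cell body sits in (or at the rim of) its track, where it may have
  # punched an un-enclosed hole: assign by majority overlap of the
  # slightly dilated cell blob with the track regions
  dil <- EBImage::makeBrush(2 * open_radius + 3, "disc")
  for (i in seq_len(nrow(cents))) {
    blob <- t(as.matrix(EBImage::dilate(t((lab == cents$id[i]) * 1), dil)))
    hit <- regions$labels[blob > 0]
    hit <- hit[hit > 0]
    if (length(hit) > 0) {
      reg <- as.integer(names(which.max(table(hit))))
      counts[reg] <- counts[reg] + 1L
    }
  }
  counts
}

#' Keep only single-cell tracks
#'
#' Applies the acceptance rule of the PKT analysis: migratory tracks
#' without a cell, or with more than one cell, are excluded.
#'
#' @param regions Result of [segment_tracks()].
#' @param cell_counts Integer vector from [detect_cell_bodies()], one entry
#'   per region.
#' @return List with `labels` (relabeled accepted regions), `accepted_ids`
#'   (original ids kept), `n_accepted` and `n_rejected`.
#' @export
accept_tracks <- function(regions, cell_counts) {
  stop_if_not(length(cell_counts) == regions$n,
              "cell_counts length must equal the number of regions")
  keep <- which(cell_counts == 1L)
  new <- matrix(0L, nrow(regions$labels), ncol(regions$labels))
  for (j in seq_along(keep)) new[regions$labels == keep[j]] <- j
  list(labels = new, accepted_ids = keep,
       n_accepted = length(keep),
       n_rejected = regions$n - length(keep))
}

#' Measure the morphometry of one track mask
#'
#' Computes the eight track parameters: net area (cleared-pixel count),
#' gross area (convex-hull area over pixel squares), ellipse-equivalent
#' major and minor axes (second central moments), axial ratio
#' (major/minor), perimeter (corner-corrected boundary chain length),
#' roughness `perimeter² / (4π · net_area)` (1 for a disc, larger for
#' ragged or elongated outlines), and solidity (net/gross).
#'
#' @param mask Non-empty logical matrix of one connected region.
#' @return One-row data.frame with columns `net_area`, `gross_area`,
#'   `major_axis`, `minor_axis`, `axial_ratio`, `roughness`, `perimeter`,
#'   `solidity`.
#' @examples
#' disc <- outer(1:61, 1:61, function(y, x) (y - 31)^2 + (x - 31)^2 <= 20^2)
#' measure_track(disc)
#' @export
measure_track <- function(mask) {
  stop_if_not(is.matrix(mask) && any(mask), "`mask` must be a non-empty mask")
  mask <- mask != 0
  net <- sum(mask)
  gross <- mask_hull_area(mask)
  axes <- mask_axes(mask)
  per <- mask_perimeter(mask)
  data.frame(net_area = net,
             gross_area = gross,
             major_axis = unname(axes["major"]),
             minor_axis = unname(axes["minor"]),
             axial_ratio = unname(axes["major"] / axes["minor"]),
             roughness = max(1, per^2 / (4 * pi * net)),
             perimeter = per,
             solidity = net / gross)
}

#' Quantify one well montage into accepted-track features
#'
#' Composes [segment_tracks()], [detect_cell_bodies()], [accept_tracks()]
#' and [measure_track()] into a per-well record.
#'
#' @param montage Image matrix, or a file path to a TIFF/PNG readable by
#'   [read_image()].
#' @param layout_entry One row of a [plate_layout()] (supplies `plate_id`,
#'   `well_id`, `treatment`).
#' @param n_images Number of tiles in the montage (default 36 = 6 x 6).
#' @param ... Passed to [segment_tracks()].
#' @return A `well_record` list: `plate_id`, `well_id`, `treatment`,
#'   `n_images`, `tracks` (feature data.frame of accepted tracks),
#'   `n_rejected`, `qc_warning`.
#' @export
quantify_well <- function(montage, layout_entry, n_images = 36L, ...) {
  if (is.character(montage)) montage <- read_image(montage)
  regions <- segment_tracks(montage, ...)
  counts <- detect_cell_bodies(montage, regions)
  acc <- accept_tracks(regions, counts)
  feats <- lapply(seq_len(acc$n_accepted), function(j) {
    measure_track(acc$labels == j)
  })
  tracks <- if (length(feats) > 0) {
    cbind(data.frame(plate_id = layout_entry$plate_id,
                     well_id = layout_entry$well_id,
                     track_id = seq_along(feats),
                     stringsAsFactors = FALSE),
          do.call(rbind, feats),
          n_cells_in_track = 1L)
  } else {
    empty_feature_table()
  }
  structure(list(plate_id = layout_entry$plate_id,
                 well_id = layout_entry$well_id,
                 treatment = layout_entry$treatment,
                 n_images = as.integer(n_images),
                 tracks = tracks,
                 n_rejected = acc$n_rejected,
                 qc_warning = regions$qc_warning),
            class = "well_record")
}

#' Read a single-channel image from disk
#'
#' Reads TIFF (via the tiff package) or PNG images into a numeric matrix
#' (`[y, x]`, values in `[0, 1]`); multi-channel input is averaged.
#'
#' @param path Image file path.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image file: ", path, call. = FALSE)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)           # already [y, x]
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  } else {
    img <- as.array(EBImage::readImage(path))  # [x, y(, c)]
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    img <- t(img)
  }
  img
}

#' Write a single-channel image (or stack) to TIFF
#'
#' @param img Matrix (`[y, x]`) or list of matrices (one page per frame).
#' @param path Output file path.
#' @param bits Bits per sample (8 or 16).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  if (is.matrix(img)) img <- list(img)
  tiff::writeTIFF(img, path, bits.per.sample = bits)
  invisible(path)
}
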