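#' The eight PKT track parameters
#'
#' @return Character vector of the parameter names quantified per track.
#' @export
pkt_parameters <- function() {
  c("net_area", "gross_area", "major_axis", "minor_axis", "axial_ratio",
    "roughness", "perimeter", "solidity")
}

#' Robust Z-scores of one well against pooled mock tracks
#'
#' For each track parameter, computes
#' \deqn{Z = \frac{\mathrm{median}(treatment) - \mathrm{median}(mock)}
#'             {1.4826 \cdot \mathrm{MAD}(mock)}}
#' where the mock statistics are taken over the pooled track-level values
#' of the plate's mock wells. The 1.4826 factor makes the MAD a consistent
#' scale estimate under normality.
#'
#' @param well_tracks Data.frame of the treatment well's accepted-track
#'   features (columns as in [pkt_parameters()]).
#' @param mock_tracks Data.frame of pooled mock-well track features from
#'   the same plate (>= 10 tracks from >= 2 wells).
#' @param params Parameters to normalize (default all eight).
#' @return Named numeric vector of Z-scores.
#' @examples
#' mock <- data.frame(net_area = c(10, 12, 14, 16, 18))
#' trt <- data.frame(net_area = c(19, 20, 21))
#' robust_z(trt, mock, params = "net_area")  # (20 - 14) / (1.4826 * 2)
#' @export
robust_z <- function(well_tracks, mock_tracks, params = pkt_parameters()) {
  vapply(params, function(p) {
    m <- mock_tracks[[p]]
    s <- stats::mad(m, constant = 1.4826)
    if (!is.finite(s) || s == 0) {
      stop("degenerate mock spread (MAD = 0) for parameter: ", p,
           call. = FALSE)
    }
    (median(well_tracks[[p]]) - median(m)) / s
  }, numeric(1))
}

#' Per-well profiles: raw medians and robust Z-scores
#'
#' Builds the per-well profile table for a whole screen: per-parameter raw
#' well medians, robust Z-scores against the plate's pooled mock tracks
#' (computed per plate), track and image counts, and a QC flag.
#'
#' @param features Per-track feature table (as from [quantify_well()] or
#'   [generate_screen_plates()]).
#' @param layout `plate_layout` rows covering every (plate, well).
#' @param well_info Optional data.frame with `plate_id`, `well_id`,
#'   `n_images`; wells default to 36 images.
#' @param params Parameters to profile.
#' @param min_mock_tracks Minimum pooled mock tracks per plate (default 10).
#' @return Data.frame with one row per well: identity columns, `n_tracks`,
#'   `n_images`, `qc_pass` (initially `TRUE`), `raw_<param>` and
#'   `z_<param>` columns.
#' @export
well_profiles <- function(features, layout, well_info = NULL,
                          params = pkt_parameters(),
                          min_mock_tracks = 10) {
  lay <- as.data.frame(layout)
  out <- list()
  for (pid in unique(lay$plate_id)) {
    lp <- lay[lay$plate_id == pid, , drop = FALSE]
    fp <- features[features$plate_id == pid, , drop = FALSE]
    mock_wells <- lp$well_id[lp$treatment == "mock"]
    stop_if_not(length(mock_wells) >= 2,
                sprintf("plate %s has fewer than 2 mock wells", pid))
    mock_tracks <- fp[fp$well_id %in% mock_wells, , drop = FALSE]
    stop_if_not(nrow(mock_tracks) >= min_mock_tracks,
                sprintf("plate %s has fewer than %d pooled mock tracks",
                        pid, min_mock_tracks))
    for (i in seq_len(nrow(lp))) {
      wt <- fp[fp$well_id == lp$well_id[i], , drop = FALSE]
      raw <- vapply(params, function(p) {
        if (nrow(wt) == 0) NA_real_ else median(wt[[p]])
      }, numeric(1))
      z <- if (nrow(wt) == 0) {
        setNames(rep(NA_real_, length(params)), params)
      } else {
        robust_z(wt, mock_tracks, params)
      }
      n_img <- 36L
      if (!is.null(well_info)) {
        m <- well_info$plate_id == pid & well_info$well_id == lp$well_id[i]
        if (any(m)) n_img <- well_info$n_images[which(m)[1]]
      }
      row <- data.frame(plate_id = pid, well_id = lp$well_id[i],
                        treatment = lp$treatment[i],
                        sirna_kind = lp$sirna_kind[i],
                        technical = lp$technical[i],
                        biological = lp$biological[i],
                        cell_line = lp$cell_line[i],
                        n_tracks = nrow(wt), n_images = n_img,
                        qc_pass = TRUE, stringsAsFactors = FALSE)
      row[paste0("raw_", params)] <- as.list(raw)
      row[paste0("z_", params)] <- as.list(z)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Well-level QC: minimum accepted-track count
#'
#' Wells with fewer than `min_tracks` accepted tracks are marked
#' `qc_pass = FALSE` and excluded from all downstream calls.
#'
#' @param profiles Data.frame from [well_profiles()] (needs `n_tracks` and
#'   `qc_pass`).
#' @param min_tracks Threshold (default 10; a well with exactly 10 is kept).
#' @return The profiles with `qc_pass` updated.
#' @export
apply_well_qc <- function(profiles, min_tracks = 10) {
  profiles$qc_pass <- profiles$qc_pass & profiles$n_tracks >= min_tracks
  profiles
}

#' Aggregate well profiles over replicates
#'
#' Averages the robust Z-scores (and raw medians) of each treatment over
#' its available replicate wells (mean over replicates, minimum
#' `min_replicates` present), sums track and image counts, and applies the
#' knockdown-level QC: treatments with fewer than `min_images` images or
#' fewer than the cell-line-specific minimum of accepted tracks (summed
#' over replicates; 60 for Hs578T, 150 for MDA-MB-231) are excluded.
#'
#' @param profiles Well-profile data.frame after [apply_well_qc()].
#' @param cell_line Cell line of the screen; must have an entry in
#'   `min_tracks_by_line` (or supply `min_tracks` directly).
#' @param min_images Minimum summed image count (default 3).
#' @param min_tracks_by_line Named defaults for the track-count minimum.
#' @param min_tracks Optional explicit track minimum overriding the table.
#' @param min_replicates Minimum replicate wells present (default 2).
#' @param params Parameters aggregated.
#' @return Data.frame with one row per treatment: mean `z_*`, mean
#'   `raw_*`, summed `n_tracks` / `n_images`, `n_replicates`, `qc_pass`.
#' @export
aggregate_replicates <- function(profiles,
                                 cell_line = unique(profiles$cell_line),
                                 min_images = 3,
                                 min_tracks_by_line = c("Hs578T" = 60,
                                                        "MDA-MB-231" = 150),
                                 min_tracks = NULL,
                                 min_replicates = 2,
                                 params = pkt_parameters()) {
  stop_if_not(length(cell_line) == 1, "profiles must be from one cell line")
  if (is.null(min_tracks)) {
    if (!cell_line %in% names(min_tracks_by_line)) {
      stop("no track-count minimum known for cell line '", cell_line,
           "'; supply `min_tracks`", call. = FALSE)
    }
    min_tracks <- min_tracks_by_line[[cell_line]]
  }
  ok <- profiles[profiles$qc_pass, , drop = FALSE]
  out <- lapply(split(ok, ok$treatment), function(g) {
    row <- data.frame(treatment = g$treatment[1], cell_line = cell_line,
                      n_replicates = nrow(g),
                      n_tracks = sum(g$n_tracks),
                      n_images = sum(g$n_images),
                      stringsAsFactors = FALSE)
    for (p in params) {
      row[[paste0("z_", p)]] <- mean(g[[paste0("z_", p)]])
      row[[paste0("raw_", p)]] <- mean(g[[paste0("raw_", p)]])
    }
    row
  })
  agg <- do.call(rbind, out)
  rownames(agg) <- NULL
  agg$qc_pass <- agg$n_replicates >= min_replicates &
    agg$n_images >= min_images & agg$n_tracks >= min_tracks
  agg
}

#' Migratory phenotype thresholds
#'
#' The five phenotype rule-sets, combining raw well-median thresholds (in
#' quantifier-native units, px-based) and robust Z-score thresholds. All
#' conditions within a class are conjunctive; classes are tried in the
#' listed order and the first match wins.
#'
#' @return A list with `version` and `classes` (each class a list of
#'   conditions `var` / `op` / `cut`).
#' @export
phenotype_thresholds <- function() {
  cond <- function(var, op, cut) list(var = var, op = op, cut = cut)
  list(
    version = "printed-v1",
    classes = list(
      small = list(cond("z_net_area", "<", -4)),
      small_round = list(cond("raw_net_area", "<", 8000),
                         cond("raw_axial_ratio", "<", 1.7),
                         cond("z_net_area", "<", -1),
                         cond("z_axial_ratio", "<", -3)),
      big_round = list(cond("raw_net_area", ">", 8000),
                       cond("raw_axial_ratio", "<", 1.7),
                       cond("z_net_area", ">", 1),
                       cond("z_axial_ratio", "<", -4)),
      long_rough = list(cond("raw_axial_ratio", ">", 2.4),
                        cond("raw_major_axis", ">", 200),
                        cond("raw_roughness", ">", 5),
                        cond("z_axial_ratio", ">", 1),
                        cond("z_major_axis", ">", 1)),
      long_smooth = list(cond("raw_axial_ratio", ">", 2.1),
                         cond("raw_major_axis", ">", 180),
                         cond("raw_roughness", "<", 5))
    )
  )
}

#' Classify a migratory phenotype from an aggregated profile
#'
#' Evaluates the five phenotype rule-sets on a replicate-aggregated well
#' profile. All matching classes are recorded; the primary class is the
#' first match in the threshold table's order, or `"unclassified"` if no
#' rule-set matches.
#'
#' @param profile One aggregated profile row (or named list) carrying the
#'   `raw_*` and `z_*` values referenced by the thresholds.
#' @param thresholds Threshold table from [phenotype_thresholds()].
#' @return List with `primary_class`, `all_matching_classes` (character,
#'   possibly empty) and `thresholds_version`.
#' @export
classify_phenotype <- function(profile, thresholds = phenotype_thresholds()) {
  profile <- as.list(profile)
  matches <- character(0)
  for (cls in names(thresholds$classes)) {
    conds <- thresholds$classes[[cls]]
    ok <- TRUE
    for (cd in conds) {
      v <- profile[[cd$var]]
      if (is.null(v) || is.na(v)) {
        stop("profile is missing parameter: ", cd$var, call. = FALSE)
      }
      hit <- switch(cd$op, "<" = v < cd$cut, ">" = v > cd$cut,
                    stop("unknown op: ", cd$op))
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) matches <- c(matches, cls)
  }
  list(primary_class = if (length(matches)) matches[1] else "unclassified",
       all_matching_classes = matches,
       thresholds_version = thresholds$version)
}

#' Classify all treatments of an aggregated screen
#'
#' @param aggregated Data.frame from [aggregate_replicates()]; only
#'   `qc_pass` rows are classified (others come back `"excluded"`).
#' @param thresholds Threshold table.
#' @return Data.frame: `treatment`, `cell_line`, `primary_class`,
#'   `all_matching_classes` (comma-separated), `thresholds_version`.
#' @export
classify_phenotypes <- function(aggregated,
                                thresholds = phenotype_thresholds()) {
  rows <- lapply(seq_len(nrow(aggregated)), function(i) {
    r <- aggregated[i, , drop = FALSE]
    if (!r$qc_pass) {
      return(data.frame(treatment = r$treatment, cell_line = r$cell_line,
                        primary_class = "excluded", all_matching_classes = "",
                        thresholds_version = thresholds$version,
                        stringsAsFactors = FALSE))
    }
    cl <- classify_phenotype(r, thresholds)
    data.frame(treatment = r$treatment, cell_line = r$cell_line,
               primary_class = cl$primary_class,
               all_matching_classes = paste(cl$all_matching_classes,
                                            collapse = ","),
               thresholds_version = cl$thresholds_version,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call primary hits and the cross-line overlap set
#'
#' A primary hit is any (non-control) treatment whose aggregated profile
#' falls into one of the five phenotype classes. The overlap set contains
#' genes hit in both cell lines with the same phenotype class.
#'
#' @param calls Classification data.frame from [classify_phenotypes()],
#'   covering one or two cell lines.
#' @return List with `hits` (data.frame treatment/cell_line/class) and
#'   `overlap` (data.frame treatment/class; empty unless two lines given).
#' @export
call_primary_hits <- function(calls) {
  hits <- calls[!calls$primary_class %in% c("unclassified", "excluded") &
                  !calls$treatment %in% c("mock", "control"), , drop = FALSE]
  hits <- hits[, c("treatment", "cell_line", "primary_class")]
  rownames(hits) <- NULL
  lines <- unique(calls$cell_line)
  overlap <- hits[0, c("treatment", "primary_class")]
  if (length(lines) == 2) {
    a <- hits[hits$cell_line == lines[1], ]
    b <- hits[hits$cell_line == lines[2], ]
    overlap <- merge(a[, c("treatment", "primary_class")],
                     b[, c("treatment", "primary_class")],
                     by = c("treatment", "primary_class"))
  }
  list(hits = hits, overlap = overlap)
}

#' PCA of the phenotype Z-score matrix
#'
#' Column-standardized principal component analysis of the treatments x
#' parameters Z matrix, used to visualize the migratory phenotype space.
#' Components are ordered by decreasing explained variance; signs are fixed
#' by making the largest-magnitude loading of each component positive.
#'
#' @param z Numeric matrix (treatments in rows, parameters in columns), no
#'   missing values; constant columns are dropped with a warning.
#' @return List with `scores`, `loadings`, `explained_variance`
#'   (proportions) and `dropped` (names of constant columns).
#' @export
pca_phenotypes <- function(z) {
  z <- as.matrix(z)
  stop_if_not(nrow(z) >= 2 && ncol(z) >= 2,
              "need at least 2 treatments and 2 parameters")
  stop_if_not(!anyNA(z), "Z matrix must not contain missing values")
  if (is.null(colnames(z))) colnames(z) <- paste0("V", seq_len(ncol(z)))
  sds <- apply(z, 2, sd)
  dropped <- colnames(z)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    z <- z[, sds > 0, drop = FALSE]
  }
  stop_if_not(ncol(z) >= 2, "fewer than 2 non-constant parameters")
  pc <- prcomp(z, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       dropped = dropped)
}

#' Validate a hit by siRNA deconvolution
#'
#' A SMARTpool hit is validated when the pool and at least two of its four
#' single siRNAs show significant effects: a profile is significant on a
#' tested parameter when `|Z| >= z_cut`, and a single siRNA only counts
#' when its significant effect has the same sign as the SMARTpool's Z on
#' that parameter.
#'
#' @param pool_z Named Z vector of the SMARTpool profile over the tested
#'   parameters.
#' @param singles_z List of up to 4 named Z vectors (one per single siRNA);
#'   `NULL` entries are counted as non-significant and flagged.
#' @param params Tested parameters (default net area and axial ratio).
#' @param z_cut Significance cut-off on |Z| (default 2).
#' @param gene Optional gene name carried through.
#' @return List with `gene`, `pool_z`, `singles_z`,
#'   `n_significant_singles`, `pool_significant`, `valid`,
#'   `missing_singles`.
#' @export
validate_deconvolution <- function(pool_z, singles_z,
                                   params = c("net_area", "axial_ratio"),
                                   z_cut = 2, gene = NA_character_) {
  stop_if_not(all(params %in% names(pool_z)),
              "pool_z must carry all tested parameters")
  pz <- pool_z[params]
  pool_sig <- any(abs(pz) >= z_cut)
  missing <- which(vapply(singles_z, is.null, logical(1)))
  n_sig <- 0L
  for (sv in singles_z) {
    if (is.null(sv)) next
    sz <- sv[params]
    conc <- abs(sz) >= z_cut & sign(sz) == sign(pz) & sign(pz) != 0
    if (any(conc, na.rm = TRUE)) n_sig <- n_sig + 1L
  }
  list(gene = gene, pool_z = pz, singles_z = singles_z,
       n_significant_singles = n_sig,
       pool_significant = pool_sig,
       valid = pool_sig && n_sig >= 2L,
       missing_singles = missing)
}
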