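# Feature-level screen simulator: draws per-track morphometry directly from
# a multivariate log-normal so the normalization/classification stages can be
# exercised at plate scale without rendering images.

.base_feature_medians <- c(net_area = 10000, major_axis = 220,
                           axial_ratio = 2.0, roughness = 3.0)
.base_feature_sdlog <- c(net_area = 0.15, major_axis = 0.10,
                         axial_ratio = 0.10, roughness = 0.12)

#' Simulate a full PKT screen at the feature level
#'
#' Generates per-track morphometry tables for a multi-plate siRNA screen
#' with known, planted motility effects. Track features (net area, major
#' axis, axial ratio, roughness, plus the derived minor axis, perimeter,
#' gross area and solidity) are drawn from log-normal distributions whose
#' medians are shifted multiplicatively per gene effect; per-well track
#' counts are Poisson so the track-count QC filters are exercisable. The
#' output schema is identical to [quantify_well()] / [measure_track()]
#' output, so the normalization and classification stages cannot tell
#' simulated from imaged data.
#'
#' @param genes Character vector of gene names placed on each plate
#'   (<= 94 with the default two mock wells).
#' @param planted_effects Named list: for each affected gene, a named
#'   numeric vector of multipliers on any of `net_area`, `major_axis`,
#'   `axial_ratio`, `roughness`, `n_tracks`. Genes not listed get identity
#'   effects. Referencing a gene absent from `genes` is an error.
#' @param n_plates Number of plates per replicate; genes are split evenly
#'   across plates. `0` returns empty tables.
#' @param replicates Data.frame with columns `technical` and `biological`
#'   (defaults to the full 2 x 2 design).
#' @param cell_line Cell line label attached to all plates.
#' @param mean_tracks Mean accepted-track count per well (Poisson).
#' @param n_images Images per well montage (6 x 6 tiling by default).
#' @param well_sdlog Log-scale SD of well-to-well median jitter.
#' @param track_sdlog Named log-scale SDs of track-level feature noise
#'   (defaults tuned so mock track-level spread makes the screen's
#'   Z-thresholds discriminative).
#' @param seed Master integer seed; per-plate/per-well streams are derived
#'   by counter-based splitting, so any subset of plates is reproducible.
#'
#' @return A list with elements
#'   \describe{
#'     \item{features}{per-track feature data.frame (`plate_id`, `well_id`,
#'       `track_id`, the eight features, `n_cells_in_track`).}
#'     \item{layouts}{combined `plate_layout` rows for all plates.}
#'     \item{well_info}{per-well `n_images` and accepted/rejected counts.}
#'     \item{ground_truth}{planted multipliers per well plus the seed.}
#'   }
#' @examples
#' sim <- generate_screen_plates(genes = paste0("G", 1:10),
#'   planted_effects = list(G1 = c(net_area = 0.2)), seed = 1)
#' head(sim$features)
#' @export
generate_screen_plates <- function(genes,
                                   planted_effects = list(),
                                   n_plates = 1L,
                                   replicates = expand.grid(technical = 1:2,
                                                            biological = 1:2),
                                   cell_line = "Hs578T",
                                   mean_tracks = 120,
                                   n_images = 36L,
                                   well_sdlog = 0.02,
                                   track_sdlog = .base_feature_sdlog,
                                   seed = 1L) {
  stop_if_not(is.numeric(n_plates) && n_plates >= 0, "`n_plates` must be >= 0")
  unknown <- setdiff(names(planted_effects), genes)
  if (length(unknown) > 0) {
    stop("planted effect references unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_par <- setdiff(unlist(lapply(planted_effects, names)),
                     c(names(.base_feature_medians), "n_tracks"))
  if (length(bad_par) > 0) {
    stop("unknown effect parameter(s): ", paste(bad_par, collapse = ", "),
         call. = FALSE)
  }

  empty <- list(
    features = empty_feature_table(),
    layouts = plate_layout("none", character(0))[0, ],
    well_info = data.frame(plate_id = character(0), well_id = character(0),
                           n_images = integer(0), n_rejected = integer(0)),
    ground_truth = list(planted_effects = planted_effects, seed = seed,
                        well_effects = NULL)
  )
  if (n_plates == 0) return(empty)

  gene_groups <- split(genes, rep(seq_len(n_plates),
                                  length.out = length(genes)))
  feats <- list(); lays <- list(); infos <- list(); gts <- list()
  for (r in seq_len(nrow(replicates))) {
    tech <- replicates$technical[r]; biol <- replicates$biological[r]
    for (p in seq_len(n_plates)) {
      pid <- sprintf("P%02d_T%d_B%d", p, tech, biol)
      lay <- plate_layout(pid, gene_groups[[p]], technical = tech,
                          biological = biol, cell_line = cell_line)
      plate_seed <- split_seed(seed, r, p)
      sim <- simulate_plate_features(lay, planted_effects, mean_tracks,
                                     n_images, well_sdlog, track_sdlog,
                                     plate_seed)
      feats[[length(feats) + 1L]] <- sim$features
      lays[[length(lays) + 1L]] <- lay
      infos[[length(infos) + 1L]] <- sim$well_info
      gts[[length(gts) + 1L]] <- sim$well_effects
    }
  }
  list(features = do.call(rbind, feats),
       layouts = do.call(rbind, lays),
       well_info = do.call(rbind, infos),
       ground_truth = list(planted_effects = planted_effects, seed = seed,
                           well_effects = do.call(rbind, gts)))
}

# One plate's worth of track features.
simulate_plate_features <- function(layout, planted_effects, mean_tracks,
                                    n_images, well_sdlog, track_sdlog, seed) {
  with_seed(seed, {
    rows <- list(); info <- list(); eff_rows <- list()
    for (i in seq_len(nrow(layout))) {
      well <- layout$well_id[i]
      trt <- layout$treatment[i]
      eff <- planted_effects[[trt]]
      mult <- c(net_area = 1, major_axis = 1, axial_ratio = 1, roughness = 1,
                n_tracks = 1)
      if (!is.null(eff)) mult[names(eff)] <- eff
      n <- rpois(1, mean_tracks * mult[["n_tracks"]])
      if (n == 0) {
        rows[[i]] <- empty_feature_table()
      } else {
        med <- .base_feature_medians * mult[names(.base_feature_medians)]
        # shared well-level jitter plus independent track-level noise
        well_shift <- rnorm(4, 0, well_sdlog)
        f <- sapply(seq_along(med), function(j) {
          nm <- names(med)[j]
          med[j] * exp(well_shift[j] + rnorm(n, 0, track_sdlog[[nm]]))
        })
        if (n == 1) f <- matrix(f, nrow = 1)
        colnames(f) <- names(med)
        f <- as.data.frame(f)
        f$axial_ratio <- pmax(f$axial_ratio, 1.0)
        f$minor_axis <- f$major_axis / f$axial_ratio
        f$solidity <- pmin(0.98, 0.75 * exp(rnorm(n, 0, 0.05)))
        f$gross_area <- f$net_area / f$solidity
        f$perimeter <- sqrt(pmax(f$roughness, 1) * 4 * pi * f$net_area)
        rows[[i]] <- data.frame(plate_id = layout$plate_id[i], well_id = well,
                                track_id = seq_len(n),
                                f[, c("net_area", "gross_area", "major_axis",
                                      "minor_axis", "axial_ratio", "roughness",
                                      "perimeter", "solidity")],
                                n_cells_in_track = 1L,
                                stringsAsFactors = FALSE)
      }
      info[[i]] <- data.frame(plate_id = layout$plate_id[i], well_id = well,
                              n_images = as.integer(n_images),
                              n_rejected = 0L, stringsAsFactors = FALSE)
      eff_rows[[i]] <- data.frame(plate_id = layout$plate_id[i],
                                  well_id = well, treatment = trt,
                                  t(mult), stringsAsFactors = FALSE)
    }
    list(features = do.call(rbind, rows), well_info = do.call(rbind, info),
         well_effects = do.call(rbind, eff_rows))
  })
}

empty_feature_table <- function() {
  data.frame(plate_id = character(0), well_id = character(0),
             track_id = integer(0), net_area = numeric(0),
             gross_area = numeric(0), major_axis = numeric(0),
             minor_axis = numeric(0), axial_ratio = numeric(0),
             roughness = numeric(0), perimeter = numeric(0),
             solidity = numeric(0), n_cells_in_track = integer(0),
             stringsAsFactors = FALSE)
}

#' Read / write per-track feature tables
#'
#' Plain CSV with the canonical column set (`plate_id`, `well_id`,
#' `track_id`, `net_area`, `gross_area`, `major_axis`, `minor_axis`,
#' `axial_ratio`, `roughness`, `perimeter`, `solidity`,
#' `n_cells_in_track`). Writing then reading is value-identical.
#'
#' @param features Feature data.frame.
#' @param path CSV file path.
#' @return `read_features_csv()` returns the feature data.frame.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  needed <- names(empty_feature_table())
  missing <- setdiff(needed, names(out))
  if (length(missing) > 0) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out
}
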