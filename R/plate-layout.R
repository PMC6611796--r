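#' 96-well plate layout for a PKT screen plate
#'
#' Builds a plate layout mapping wells (A1..H12) to treatments. Every plate
#' carries at least two mock (transfection-reagent-only) wells, which define
#' the null migratory phenotype used for robust Z-score normalization.
#'
#' @param plate_id Plate identifier (text).
#' @param genes Character vector of gene (or control) names to place in
#'   non-mock wells, at most `96 - length(mock_wells)` of them.
#' @param mock_wells Well ids reserved for mock controls (>= 2).
#' @param sirna_kind siRNA reagent kind for the gene wells: `"smartpool"`
#'   (pool of four siRNAs per gene) or `"single_1"`..`"single_4"`.
#' @param technical,biological Replicate indices (1 or 2); screens run in
#'   2 technical x 2 biological replicates.
#' @param cell_line Cell line name (e.g. `"Hs578T"` or `"MDA-MB-231"`).
#'
#' @return A data.frame of class `plate_layout` with columns `plate_id`,
#'   `well_id`, `treatment`, `sirna_kind`, `technical`, `biological`,
#'   `cell_line`.
#' @examples
#' plate_layout("P1", genes = paste0("GENE", 1:10), cell_line = "Hs578T")
#' @export
plate_layout <- function(plate_id, genes,
                         mock_wells = c("A1", "B1"),
                         sirna_kind = "smartpool",
                         technical = 1L, biological = 1L,
                         cell_line = "Hs578T") {
  stop_if_not(length(mock_wells) >= 2,
              "every plate needs at least 2 mock wells")
  all_wells <- well_ids_96()
  stop_if_not(all(mock_wells %in% all_wells),
              "mock wells must use 96-well ids A1..H12")
  stop_if_not(!anyDuplicated(mock_wells), "duplicated mock well ids")
  stop_if_not(technical %in% 1:2 && biological %in% 1:2,
              "replicate indices must be 1 or 2")
  gene_wells <- setdiff(all_wells, mock_wells)
  stop_if_not(length(genes) <= length(gene_wells),
              sprintf("at most %d gene wells available", length(gene_wells)))
  wells <- c(mock_wells, gene_wells[seq_along(genes)])
  out <- data.frame(
    plate_id = plate_id,
    well_id = wells,
    treatment = c(rep("mock", length(mock_wells)), genes),
    sirna_kind = c(rep("mock", length(mock_wells)),
                   rep(sirna_kind, length.out = length(genes))),
    technical = as.integer(technical),
    biological = as.integer(biological),
    cell_line = cell_line,
    stringsAsFactors = FALSE
  )
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Standard 96-well identifiers A1..H12
#'
#' @return Character vector of the 96 well ids in row-major order.
#' @export
well_ids_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Read / write plate layouts as YAML
#'
#' @param layout A `plate_layout` data.frame (or list of them).
#' @param path File path.
#' @return `read_plate_layout()` returns a `plate_layout` data.frame.
#' @export
write_plate_layout <- function(layout, path) {
  df <- as.data.frame(layout)
  yaml::write_yaml(list(plate_id = df$plate_id[1],
                        cell_line = df$cell_line[1],
                        technical = df$technical[1],
                        biological = df$biological[1],
                        wells = lapply(seq_len(nrow(df)), function(i) {
                          list(well_id = df$well_id[i],
                               treatment = df$treatment[i],
                               sirna_kind = df$sirna_kind[i])
                        })), path)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  y <- yaml::read_yaml(path)
  wells <- do.call(rbind, lapply(y$wells, function(w) {
    data.frame(well_id = w$well_id, treatment = w$treatment,
               sirna_kind = w$sirna_kind, stringsAsFactors = FALSE)
  }))
  out <- data.frame(plate_id = y$plate_id, wells,
                    technical = as.integer(y$technical),
                    biological = as.integer(y$biological),
                    cell_line = y$cell_line, stringsAsFactors = FALSE)
  class(out) <- c("plate_layout", "data.frame")
  out
}
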