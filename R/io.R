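# TSV plumbing shared by the pipeline. All files are UTF-8,
# tab-delimited, header row, with '#'-prefixed provenance comments on top.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  v <- as.character(utils::packageVersion("mechanomir"))
  paste0("# mechanomir ", v,
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(config_hash)) paste0(" config=", config_hash))
}

write_tsv_provenance <- function(x, path, seed = NULL, config_hash = NULL) {
  readr::write_lines(provenance_header(seed, config_hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write the expression-table TSV schema
#'
#' Columns: `feature_id`, `feature_type`, `fold_change`, `p_value`, `fdr`.
#' Lines starting with `#` are provenance comments and are skipped.
#'
#' @param path File path.
#' @return A tibble (`read_expression_tsv`) or the path, invisibly.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    feature_id = "c", feature_type = "c",
                    fold_change = "d", p_value = "d", fdr = "d"))
}

#' @rdname read_expression_tsv
#' @param records Expression tibble to write.
#' @inheritParams write_wound_pair
#' @param seed,config_hash Optional provenance fields for the header.
#' @export
write_expression_tsv <- function(records, path, seed = NULL,
                                 config_hash = NULL) {
  write_tsv_provenance(records, path, seed, config_hash)
}

#' Read and write per-miRNA pathway export TSVs
#'
#' Long-format schema: `mirna`, `pathway`, `database`, `enrichment_p`,
#' `targets` (semicolon-joined gene ids; a list-column in memory).
#'
#' @param path File path.
#' @return A tibble with a `targets` list-column
#'   (`read_pathway_exports`), or the path invisibly.
#' @export
read_pathway_exports <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    mirna = "c", pathway = "c", database = "c",
                    enrichment_p = "d", targets = "c")) %>%
    dplyr::mutate(targets = stringr::str_split(.data$targets, ";"))
}

#' @rdname read_pathway_exports
#' @param exports Export tibble (with `targets` list-column) to write.
#' @param seed,config_hash Optional provenance fields for the header.
#' @export
write_pathway_exports <- function(exports, path, seed = NULL,
                                  config_hash = NULL) {
  flat <- dplyr::mutate(exports,
                        targets = purrr::map_chr(.data$targets, paste,
                                                 collapse = ";"))
  write_tsv_provenance(flat, path, seed, config_hash)
}

#' Read a wound-area table
#'
#' Columns: `condition`, `replicate_id`, `area_initial`, `area_final`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_areas_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    condition = "c", replicate_id = "c",
                    area_initial = "d", area_final = "d"))
}
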