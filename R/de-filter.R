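#' Filter an expression table to differentially expressed features
#'
#' Applies the triple threshold used to call differential expression from
#' the array analysis: `p < p_max`, `FDR < fdr_max`, and `|fold change| >
#' abs_fc_min`, all strict inequalities (boundary values are excluded).
#' Fold changes follow the signed convention of array consoles: magnitude
#' `|FC| >= 1` with the sign giving direction, so a halving is -2, not 0.5.
#'
#' @param records A data frame with columns `feature_id`, `fold_change`,
#'   `p_value`, `fdr` (and usually `feature_type`).
#' @param p_max,fdr_max,abs_fc_min Thresholds; defaults 0.05, 0.05, 2.
#' @return The retained rows as a tibble. Filtering is idempotent and
#'   order-invariant.
#' @examples
#' filter_de(mirna_de_table()) |> nrow()  # 27
#' @export
filter_de <- function(records, p_max = 0.05, fdr_max = 0.05, abs_fc_min = 2) {
  need <- c("feature_id", "fold_change", "p_value", "fdr")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort(sprintf("`records` must have columns: %s.",
                  paste(need, collapse = ", ")),
          class = "mechanomir_schema_error")
  }
  if (abs_fc_min <= 1 || p_max <= 0 || fdr_max <= 0) {
    abort("Criteria must be positive with `abs_fc_min` > 1.",
          class = "mechanomir_domain_error")
  }
  as_tibble(records) %>%
    dplyr::filter(.data$p_value < p_max, .data$fdr < fdr_max,
                  abs(.data$fold_change) > abs_fc_min)
}

#' Split a DE subset by feature type
#'
#' Partitions the filtered features into the coding-gene set (input to
#' downstream pathway-prediction tools) and the precursor-miRNA set (input
#' to the interaction analysis). Unknown feature types are routed to
#' `other` with a warning. The partition is exhaustive and disjoint.
#'
#' @param de_subset A filtered expression tibble with a `feature_type`
#'   column.
#' @return A named list of tibbles: `coding`, `precursor_mirna`, `other`.
#' @examples
#' split_by_type(filter_de(mirna_de_table()))$precursor_mirna |> nrow()
#' @export
split_by_type <- function(de_subset) {
  if (!is.data.frame(de_subset) || !"feature_type" %in% names(de_subset)) {
    abort("`de_subset` needs a `feature_type` column.",
          class = "mechanomir_schema_error")
  }
  de_subset <- as_tibble(de_subset)
  known <- c("coding", "precursor_mirna")
  if (nrow(de_subset) > 0 && any(!de_subset$feature_type %in% known)) {
    warn(sprintf("%d feature(s) with unknown feature_type routed to 'other'.",
                 sum(!de_subset$feature_type %in% known)),
         class = "mechanomir_type_warning")
  }
  list(
    coding = dplyr::filter(de_subset, .data$feature_type == "coding"),
    precursor_mirna = dplyr::filter(de_subset,
                                    .data$feature_type == "precursor_mirna"),
    other = dplyr::filter(de_subset, !.data$feature_type %in% known))
}
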