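#' Generate a synthetic differential-expression table
#'
#' Emulates the output of an upstream array analysis (one row per feature
#' with signed fold change, p-value, and FDR-adjusted p). Exactly `n_de`
#' features are generated as truly differentially expressed: `|FC|` uniform
#' in `fc_range` with random sign, and p and FDR below 0.05. The remaining
#' features are nulls built to fail the triple filter, either by a small fold
#' change (`|FC| <= 2`) or by a non-significant FDR. FDR values are assigned
#' directly, not derived from the p-values: this module emulates a table that
#' a finished multiple-testing step produced, it does not redo that step.
#'
#' @param n_features Total number of features (>= 1).
#' @param n_de Number of truly differentially expressed features
#'   (`0 <= n_de <= n_features`).
#' @param fc_range Length-2 numeric, the range of `|FC|` for DE features;
#'   the lower bound must exceed 2 so truth passes the filter.
#' @param prop_mirna Proportion of features typed as precursor miRNA; the
#'   rest are coding.
#' @param seed Integer seed.
#' @return A list of class `expression_set` with `records` (tibble:
#'   `feature_id`, `feature_type`, `fold_change`, `p_value`, `fdr`) and
#'   `truth_de_ids` (character).
#' @examples
#' es <- simulate_expression_set(200, 30, seed = 1)
#' nrow(filter_de(es$records))
#' @export
simulate_expression_set <- function(n_features, n_de,
                                    fc_range = c(2.05, 13),
                                    prop_mirna = 0.15, seed = 42L) {
  stopifnot_scalar_number(n_features, "n_features", lower = 1)
  stopifnot_scalar_number(n_de, "n_de", lower = 0, upper = n_features)
  if (length(fc_range) != 2 || fc_range[1] <= 2 || diff(fc_range) < 0) {
    abort("`fc_range` must be increasing with lower bound > 2.",
          class = "mechanomir_domain_error")
  }
  withr::with_seed(seed, {
    ids <- sprintf("FEAT%05d", seq_len(n_features))
    type <- sample(c("coding", "precursor_mirna"), n_features, replace = TRUE,
                   prob = c(1 - prop_mirna, prop_mirna))
    de_idx <- sample.int(n_features, n_de)
    is_de <- seq_len(n_features) %in% de_idx
    fc <- p <- fdr <- numeric(n_features)
    fc[is_de] <- stats::runif(n_de, fc_range[1], fc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)
    p[is_de] <- stats::runif(n_de, 1e-6, 0.049)
    fdr[is_de] <- stats::runif(n_de, 1e-6, 0.049)
    n_null <- n_features - n_de
    if (n_null > 0) {
      # two null flavours: small effect, or large effect that fails FDR
      small <- stats::runif(n_null) < 0.5
      afc <- ifelse(small, stats::runif(n_null, 1, 2),
                    stats::runif(n_null, 2.05, 8))
      fc[!is_de] <- afc * sample(c(-1, 1), n_null, replace = TRUE)
      p[!is_de] <- stats::runif(n_null, 1e-6, 1)
      fdr[!is_de] <- ifelse(small, stats::runif(n_null, 1e-6, 1),
                            stats::runif(n_null, 0.05, 1))
    }
  })
  structure(
    list(records = tibble(feature_id = ids, feature_type = type,
                          fold_change = fc, p_value = p, fdr = fdr),
         truth_de_ids = ids[is_de]),
    class = "expression_set")
}

#' Differentially regulated precursor miRNAs at 23 Pa (fixture)
#'
#' The packaged transcription of the 27 precursor miRNAs found
#' differentially regulated in LN229 cells under 23 Pa compressive stress,
#' with their signed fold changes and a flag for prior implication in
#' glioblastoma. The source table prints fold changes only; the `p_value`
#' and `fdr` columns here are synthetic placeholders (0.01) recording that
#' every entry passed the significance gates upstream.
#'
#' @return A tibble with columns `feature_id`, `feature_type`
#'   (`"precursor_mirna"`), `fold_change`, `p_value`, `fdr`,
#'   `gbm_relevant` (logical: previously implicated in GBM).
#' @examples
#' nrow(mirna_de_table())
#' @export
mirna_de_table <- function() {
  known <- tibble(
    feature_id = c("mir-31-HG", "mir-100-HG", "mir-181-A1-HG", "mir-181-B1",
                   "mir-421", "mir-423", "mir-454", "mir-548-AJ2",
                   "mir-548-AZ", "mir-548-T", "let-7i"),
    fold_change = c(-2.03, -2.63, -4.2, -2.9, -2.05, -3.28, -2.22, -2.16,
                    -2.03, -2.3, -3.35),
    gbm_relevant = TRUE)
  novel <- tibble(
    feature_id = c("mir-563", "mir-569", "mir-604", "mir-4477-B", "mir-6125",
                   "mir-6839", "mir-7978", "mir-8063", "mir-924", "mir-943",
                   "mir-3614", "mir-8085", "mir-4640", "mir-6884", "mir-3611",
                   "mir-6787"),
    fold_change = c(-2.38, -2.55, -3.06, -2.21, -2.2, -2.43, -2.78, -2.7,
                    -3.32, 2.02, 2.02, 2.06, 2.12, 2.19, 4.17, 4.95),
    gbm_relevant = FALSE)
  dplyr::bind_rows(known, novel) %>%
    dplyr::mutate(feature_type = "precursor_mirna", p_value = 0.01,
                  fdr = 0.01, .after = "feature_id")
}

#' Selected differentially regulated mRNAs at 23 Pa (fixture)
#'
#' Transcription of the selected coding genes reported differentially
#' regulated under 23 Pa compressive stress, with signed fold change and FDR.
#' The `p_value` column is a synthetic placeholder (half the FDR) since the
#' source prints FDR only.
#'
#' @return A tibble with `feature_id`, `feature_type` (`"coding"`),
#'   `fold_change`, `p_value`, `fdr`.
#' @export
mrna_de_table <- function() {
  tibble(
    feature_id = c("STC1", "TMEM45A", "CA9", "ITGA3", "FOXN2", "LY6K",
                   "CTGF", "VEGFA", "VEGFB"),
    fold_change = c(12.79, 9.64, 7.75, 2.34, -2.63, 4.83, 2.17, 3.02, 2.04),
    fdr = c(2e-4, 2e-4, 0.0011, 0.0245, 0.0386, 0.0072, 0.0314, 0.0072,
            0.0177)) %>%
    dplyr::mutate(feature_type = "coding", p_value = .data$fdr / 2,
                  .after = "feature_id")
}

# keyword vocabulary used to mint classifiable pathway names, one pool per
# functional group; every token must classify to its own group under
# pathway_group_rules() (round-trip asserted at generation time)
pathway_name_pool <- function() {
  list(
    "Cancer" = c("glioma", "pathways in cancer", "small cell lung cancer",
                 "melanoma"),
    "Motility" = c("cell projection morphogenesis", "cell migration",
                   "actin cytoskeleton organization", "focal adhesion"),
    "DNA Repair" = c("dna repair", "double-strand break repair",
                     "nucleotide excision repair", "dna damage response"),
    "Cell Cycle" = c("cell cycle checkpoint", "chromosome segregation",
                     "mitotic nuclear division", "cell cycle arrest"),
    "Apoptosis" = c("apoptotic process", "programmed cell death",
                    "intrinsic apoptotic pathway", "regulation of apoptosis"),
    "Miscellaneous" = c("ion transport", "ribosome biogenesis",
                        "lipid storage", "protein folding"),
    "Canonical" = c("mapk signaling", "wnt signaling", "hif-1 signaling",
                    "notch signaling")
  )
}

#' Generate a synthetic per-miRNA pathway/target database
#'
#' Emulates per-miRNA pathway-database exports: for each miRNA, a table of
#' significantly enriched pathways, each with a source database, an
#' enrichment p-value, and a target-gene list drawn from a supplied feature
#' universe. Pathway names are minted from group-specific keyword pools so
#' the interaction module's keyword classifier recovers the intended
#' functional group exactly (the round trip is asserted at generation time).
#'
#' @param mirnas Character vector of miRNA ids (non-empty).
#' @param feature_ids Universe of gene ids that target lists are drawn from.
#' @param n_pathways_per_group Pathways minted per functional group (>= 1).
#' @param targets_per_pathway Targets per (miRNA, pathway) row (>= 1).
#' @param groups Functional groups to include; default all seven.
#' @param databases Source-database labels; default four generic labels.
#' @param prop_significant Proportion of rows with enrichment p < 0.05
#'   (default 1, i.e. the export only lists significantly enriched pathways).
#' @param seed Integer seed.
#' @return A list of class `pathway_db` with `exports` (tibble: `mirna`,
#'   `pathway`, `database`, `enrichment_p`, `targets` list-column) and
#'   `truth_groups` (tibble: `pathway`, `group`).
#' @examples
#' db <- simulate_pathway_db(c("mir-a", "mir-b"),
#'                           feature_ids = sprintf("G%03d", 1:50), seed = 1)
#' head(db$exports)
#' @export
simulate_pathway_db <- function(mirnas, feature_ids,
                                n_pathways_per_group = 3,
                                targets_per_pathway = 8,
                                groups = names(pathway_name_pool()),
                                databases = c("KEGG", "GO-BP",
                                              "WikiPathways", "Reactome"),
                                prop_significant = 1, seed = 42L) {
  if (length(mirnas) == 0) {
    abort("`mirnas` must be non-empty.", class = "mechanomir_domain_error")
  }
  stopifnot_scalar_number(n_pathways_per_group, "n_pathways_per_group", lower = 1)
  stopifnot_scalar_number(targets_per_pathway, "targets_per_pathway", lower = 1)
  if (length(feature_ids) < targets_per_pathway) {
    abort("`feature_ids` must contain at least `targets_per_pathway` ids.",
          class = "mechanomir_domain_error")
  }
  pool <- pathway_name_pool()
  if (!all(groups %in% names(pool))) {
    abort("Unknown group in `groups`.", class = "mechanomir_domain_error")
  }
  withr::with_seed(seed, {
    truth <- purrr::map(groups, function(g) {
      tokens <- pool[[g]]
      nm <- vapply(seq_len(n_pathways_per_group), function(i) {
        tok <- tokens[((i - 1) %% length(tokens)) + 1]
        if (i > length(tokens)) paste(tok, i) else tok
      }, character(1))
      tibble(pathway = nm, group = g)
    }) %>% dplyr::bind_rows()
    got <- classify_pathway(truth$pathway)
    if (!all(got == truth$group)) {
      abort("Internal error: minted pathway name failed classifier round-trip.")
    }
    exports <- tidyr::expand_grid(mirna = mirnas, pathway = truth$pathway) %>%
      dplyr::mutate(
        database = sample(databases, dplyr::n(), replace = TRUE),
        enrichment_p = ifelse(stats::runif(dplyr::n()) < prop_significant,
                              stats::runif(dplyr::n(), 0.001, 0.049),
                              stats::runif(dplyr::n(), 0.051, 0.5)),
        targets = purrr::map(seq_len(dplyr::n()),
                             ~ sample(feature_ids, targets_per_pathway)))
  })
  structure(list(exports = exports, truth_groups = truth),
            class = "pathway_db")
}
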