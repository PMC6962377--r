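#' Default miRNA id substitution rules
#'
#' Array annotations report some miRNAs indirectly: as their host gene
#' (`-HG` entries), as a precursor variant with an identical mature sequence
#' (e.g. `mir-548-AJ2`), or as one member of an isoform pair. Before pathway
#' exports can be matched, such reported ids are substituted by the id the
#' pathway database actually indexes. These defaults cover the host-gene
#' and variant substitutions needed for the packaged 23 Pa miRNA table;
#' users can supply their own rules tibble of the same shape.
#'
#' @return A tibble with columns `reported_id`, `substituted_id`, `reason`
#'   (`host_gene`, `isoform_merge`, or `precursor_variant`).
#' @export
default_substitutions <- function() {
  tibble(
    reported_id = c("mir-31-HG", "mir-100-HG", "mir-181-A1-HG",
                    "mir-181-B1", "mir-548-AJ2", "mir-548-AZ", "mir-548-T"),
    substituted_id = c("hsa-mir-31", "hsa-mir-100", "hsa-mir-181a",
                       "hsa-mir-181b", "hsa-mir-548aj", "hsa-mir-548az",
                       "hsa-mir-548t"),
    reason = c("host_gene", "host_gene", "host_gene", "isoform_merge",
               "precursor_variant", "precursor_variant", "precursor_variant"))
}

#' Apply miRNA id substitution rules
#'
#' Maps each reported id through the rules (case-insensitively); ids with
#' no rule pass through unchanged. Conflicting rules (one reported id, two
#' targets) are a configuration error.
#'
#' @param reported_ids Character vector of ids as reported upstream.
#' @param rules A rules tibble, see [default_substitutions()].
#' @return A character vector of working ids, with a logical attribute
#'   `substituted` marking which entries were mapped.
#' @examples
#' apply_substitutions("mir-548-AJ2")  # "hsa-mir-548aj"
#' @export
apply_substitutions <- function(reported_ids, rules = default_substitutions()) {
  need <- c("reported_id", "substituted_id")
  if (!is.data.frame(rules) || !all(need %in% names(rules))) {
    abort("`rules` needs columns reported_id and substituted_id.",
          class = "mechanomir_config_error")
  }
  key <- tolower(rules$reported_id)
  if (anyDuplicated(key)) {
    dup <- rules$reported_id[duplicated(key)][1]
    conflict <- length(unique(rules$substituted_id[key == tolower(dup)])) > 1
    if (conflict) {
      abort(sprintf("Conflicting substitution rules for '%s'.", dup),
            class = "mechanomir_config_error")
    }
  }
  idx <- match(tolower(reported_ids), key)
  out <- ifelse(is.na(idx), reported_ids, rules$substituted_id[idx])
  attr(out, "substituted") <- !is.na(idx)
  out
}

#' Default pathway-group keyword rules
#'
#' Ordered inclusion/exclusion keyword rules assigning every pathway name to
#' exactly one of seven functional groups: Cancer, Motility, DNA Repair,
#' Cell Cycle, Apoptosis, Miscellaneous, Canonical. A pathway takes the
#' first group (by priority) whose include keyword it contains and none of
#' whose exclude keywords it contains; Miscellaneous is the guaranteed
#' fallback. The DNA Repair rule excludes "signaling" so that, e.g., an ATM
#' *signaling network* pathway lands in Canonical rather than DNA Repair.
#' Rules are an ordinary tibble, so a lab can version and edit its own.
#'
#' @return A tibble with `group`, `priority`, and list-columns `include`,
#'   `exclude` (lowercase substrings).
#' @export
pathway_group_rules <- function() {
  tibble(
    group = c("Motility", "Apoptosis", "Cell Cycle", "DNA Repair",
              "Cancer", "Canonical"),
    priority = 1:6,
    include = list(
      c("cell projection", "migration", "motility", "adhesion",
        "cytoskelet", "locomotion", "lamellipod", "filopod"),
      c("apopto", "programmed cell death", "anoikis"),
      c("cell cycle", "chromosom", "mitotic", "mitosis", "spindle",
        "proliferation"),
      c("dna repair", "dna damage", "excision repair", "strand break",
        "atm", "mismatch repair"),
      c("cancer", "glioma", "glioblastoma", "carcinoma", "melanoma",
        "leukemia", "tumor"),
      c("signaling", "signalling", "canonical")),
    exclude = list(character(0), character(0), character(0), "signaling",
                   character(0), character(0)))
}

#' Classify pathway names into functional groups
#'
#' Deterministic keyword classification: for each name (lowercased), the
#' first rule by priority whose include keyword matches and no exclude
#' keyword matches wins; names matching no rule fall back to
#' `"Miscellaneous"`, so the function is total.
#'
#' @param names Character vector of pathway names.
#' @param rules A rules tibble, see [pathway_group_rules()].
#' @return A character vector of group labels, same length as `names`.
#' @examples
#' classify_pathway(c("cell projection morphogenesis", "Apoptotic Process",
#'                    "zzz unmatched zzz"))
#' @export
classify_pathway <- function(names, rules = pathway_group_rules()) {
  rules <- dplyr::arrange(rules, .data$priority)
  low <- tolower(names)
  out <- rep("Miscellaneous", length(names))
  undecided <- rep(TRUE, length(names))
  for (i in seq_len(nrow(rules))) {
    inc <- rules$include[[i]]
    exc <- rules$exclude[[i]]
    hit <- undecided &
      Reduce(`|`, lapply(inc, function(k) stringr::str_detect(low, stringr::fixed(k))),
             rep(FALSE, length(low)))
    if (length(exc) > 0) {
      blocked <- Reduce(`|`, lapply(exc, function(k)
        stringr::str_detect(low, stringr::fixed(k))), rep(FALSE, length(low)))
      hit <- hit & !blocked
    }
    out[hit] <- rules$group[i]
    undecided <- undecided & !hit
  }
  out
}

# score one export row against the DE fold-change lookup
score_node_impl <- function(targets, enrichment_p, de_fc, alpha) {
  if (length(targets) == 0) {
    abort("Empty target set.", class = "mechanomir_domain_error")
  }
  de_hits <- intersect(targets, names(de_fc))
  n_t <- length(unique(targets))
  n_de <- length(de_hits)
  tibble(
    intersects = enrichment_p < alpha,
    n_targets = n_t, n_de_targets = n_de,
    percent_overlap = 100 * n_de / n_t,
    cumulative_abs_fc = sum(abs(de_fc[de_hits])))
}

#' Score miRNA x pathway interaction nodes
#'
#' The core cross-referencing step: every (miRNA, pathway) row of the
#' pathway exports is scored against the differentially expressed mRNA
#' list. Per node: `intersects` — whether the export's enrichment p falls
#' below `alpha` (significance is read from the export, as supplied by the
#' pathway database, not recomputed); `percent_overlap` — differentially
#' regulated targets as a percentage of all targets in the pathway;
#' `cumulative_abs_fc` — the sum of `|FC|` over the differentially
#' regulated targets. Duplicate rows are consolidated first: identical
#' (miRNA, pathway, database) rows merge by target-set union and minimum
#' enrichment p, then pathways listed by several databases collapse to one
#' node per (miRNA, pathway). miRNA ids are passed through the substitution
#' rules, and each pathway is tagged with its functional group.
#'
#' @param exports Export tibble (`mirna`, `pathway`, `database`,
#'   `enrichment_p`, `targets` list-column), e.g.
#'   `simulate_pathway_db()$exports` or [read_pathway_exports()].
#' @param de A data frame of differentially expressed mRNAs with
#'   `feature_id` and `fold_change` (signed), e.g. the coding set from
#'   [split_by_type()].
#' @param rules Pathway-group keyword rules.
#' @param substitutions miRNA substitution rules, or `NULL` to skip.
#' @param alpha Enrichment significance level for the intersection flag.
#' @return A tibble of class `interaction_nodes`: one row per
#'   (miRNA, pathway) with `mirna`, `pathway`, `group`, `database`,
#'   `enrichment_p`, `intersects`, `n_targets`, `n_de_targets`,
#'   `percent_overlap`, `cumulative_abs_fc`.
#' @examples
#' db <- simulate_pathway_db("mir-x", feature_ids = sprintf("G%02d", 1:20),
#'                           seed = 1)
#' de <- tibble::tibble(feature_id = sprintf("G%02d", 1:5),
#'                      fold_change = c(3, -2.5, 4, 2.2, -6))
#' score_interactions(db$exports, de)
#' @export
score_interactions <- function(exports, de, rules = pathway_group_rules(),
                               substitutions = default_substitutions(),
                               alpha = 0.05) {
  need <- c("mirna", "pathway", "database", "enrichment_p", "targets")
  if (!is.data.frame(exports) || !all(need %in% names(exports))) {
    abort(sprintf("`exports` must have columns: %s.",
                  paste(need, collapse = ", ")),
          class = "mechanomir_schema_error")
  }
  if (!all(c("feature_id", "fold_change") %in% names(de))) {
    abort("`de` needs columns feature_id and fold_change.",
          class = "mechanomir_schema_error")
  }
  de_fc <- stats::setNames(de$fold_change, de$feature_id)
  exports <- as_tibble(exports)
  if (!is.null(substitutions)) {
    exports$mirna <- as.character(apply_substitutions(exports$mirna,
                                                      substitutions))
  }
  consolidated <- exports %>%
    dplyr::group_by(.data$mirna, .data$pathway, .data$database) %>%
    dplyr::summarise(
      enrichment_p = min(.data$enrichment_p),
      targets = list(unique(unlist(.data$targets))), .groups = "drop") %>%
    dplyr::group_by(.data$mirna, .data$pathway) %>%
    dplyr::summarise(
      database = paste(sort(unique(.data$database)), collapse = ";"),
      enrichment_p = min(.data$enrichment_p),
      targets = list(unique(unlist(.data$targets))), .groups = "drop")
  scores <- purrr::map2(consolidated$targets, consolidated$enrichment_p,
                        ~ score_node_impl(.x, .y, de_fc, alpha)) %>%
    dplyr::bind_rows()
  out <- consolidated %>%
    dplyr::mutate(group = classify_pathway(.data$pathway, rules),
                  .after = "pathway") %>%
    dplyr::select(-"targets") %>%
    dplyr::bind_cols(scores)
  class(out) <- c("interaction_nodes", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Number of miRNAs intersecting each pathway
#'
#' Column sums of the intersection view of the interaction matrix: for each
#' pathway, how many miRNAs have a significant target-enrichment in it.
#' Supports the "pathways intersecting more than k miRNAs" query.
#'
#' @param nodes An [score_interactions()] result.
#' @param pathway Optional single pathway name; if given, returns that
#'   pathway's count (unknown name is an error).
#' @return A tibble (`pathway`, `group`, `n_mirna_intersecting`) sorted
#'   descending, or a single count if `pathway` is given.
#' @export
count_intersections <- function(nodes, pathway = NULL) {
  stopifnot(inherits(nodes, "interaction_nodes"))
  tab <- nodes %>%
    dplyr::group_by(.data$pathway, .data$group) %>%
    dplyr::summarise(n_mirna_intersecting = sum(.data$intersects),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n_mirna_intersecting))
  if (is.null(pathway)) return(tab)
  hit <- tab$n_mirna_intersecting[tab$pathway == pathway]
  if (length(hit) == 0) {
    abort(sprintf("Pathway '%s' not present in any export.", pathway),
          class = "mechanomir_lookup_error")
  }
  hit
}

#' Aggregate node values by pathway group, miRNA, or GBM-relevance group
#'
#' Group means of a node metric with SEM and n. Means run over *all* nodes
#' present in the exports, including zero-overlap nodes — a pathway a miRNA
#' targets but whose targets are not differentially regulated still counts
#' as a zero, which is what keeps group means small and comparable.
#'
#' @param nodes An [score_interactions()] result.
#' @param by `"pathway_group"`, `"mirna"`, or `"relevance_group"`.
#' @param metric `"percent_overlap"` or `"cumulative_abs_fc"`.
#' @param relevance For `by = "relevance_group"`: a two-class miRNA
#'   annotation tibble (`mirna`, `relevance_group`).
#' @return A tibble with the grouping column, `n`, `mean`, `sem`.
#' @export
aggregate_interactions <- function(nodes,
                                   by = c("pathway_group", "mirna",
                                          "relevance_group"),
                                   metric = c("percent_overlap",
                                              "cumulative_abs_fc"),
                                   relevance = NULL) {
  stopifnot(inherits(nodes, "interaction_nodes"))
  by <- match.arg(by)
  metric <- match.arg(metric)
  key <- switch(by, pathway_group = "group", mirna = "mirna",
                relevance_group = "relevance_group")
  if (by == "relevance_group" && !"relevance_group" %in% names(nodes)) {
    if (is.null(relevance)) {
      abort("Supply `relevance` (mirna, relevance_group) for this grouping.",
            class = "mechanomir_config_error")
    }
    nodes <- dplyr::inner_join(nodes, relevance, by = "mirna")
  }
  nodes %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[metric]]),
                     sem = sem(.data[[metric]]), .groups = "drop") %>%
    dplyr::mutate(metric = metric)
}

#' Compare node-metric distributions across groups
#'
#' One-way ANOVA over the per-node values with Tukey-Kramer HSD pairwise
#' comparisons at `alpha = 0.05` (the Tukey procedure on possibly unequal
#' group sizes). Groups with fewer than 2 nodes are dropped with a warning;
#' if the residual variance is degenerate the test is skipped and reported
#' as such.
#'
#' @inheritParams aggregate_interactions
#' @param alpha Significance level (default 0.05).
#' @return A list of class `interaction_group_test`: `anova_p`, `tukey`
#'   (tibble: `comparison`, `diff`, `lwr`, `upr`, `p_adj`, `significant`),
#'   `skipped` flag, plus the grouping/metric used. `tidy()` returns the
#'   pairwise table, `glance()` the omnibus row.
#' @export
compare_interaction_groups <- function(nodes,
                                       by = c("pathway_group", "mirna",
                                              "relevance_group"),
                                       metric = c("percent_overlap",
                                                  "cumulative_abs_fc"),
                                       relevance = NULL, alpha = 0.05) {
  stopifnot(inherits(nodes, "interaction_nodes"))
  by <- match.arg(by)
  metric <- match.arg(metric)
  key <- switch(by, pathway_group = "group", mirna = "mirna",
                relevance_group = "relevance_group")
  if (by == "relevance_group" && !"relevance_group" %in% names(nodes)) {
    if (is.null(relevance)) {
      abort("Supply `relevance` (mirna, relevance_group) for this grouping.",
            class = "mechanomir_config_error")
    }
    nodes <- dplyr::inner_join(nodes, relevance, by = "mirna")
  }
  df <- tibble(value = nodes[[metric]], grp = nodes[[key]]) %>%
    dplyr::group_by(.data$grp) %>% dplyr::filter(dplyr::n() >= 2) %>%
    dplyr::ungroup()
  dropped <- dplyr::n_distinct(nodes[[key]]) - dplyr::n_distinct(df$grp)
  if (dropped > 0) {
    warn(sprintf("%d group(s) with < 2 nodes dropped from the comparison.",
                 dropped), class = "mechanomir_group_warning")
  }
  if (dplyr::n_distinct(df$grp) < 2) {
    abort("Need >= 2 groups with >= 2 nodes each.",
          class = "mechanomir_domain_error")
  }
  out <- list(by = by, metric = metric, alpha = alpha, skipped = FALSE,
              anova_p = NA_real_, tukey = tibble())
  if (stats::sd(df$value) == 0 ||
      all(tapply(df$value, df$grp, stats::sd) == 0)) {
    out$skipped <- TRUE
    class(out) <- "interaction_group_test"
    return(out)
  }
  df$grp <- factor(df$grp)
  fit <- stats::aov(value ~ grp, data = df)
  out$anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  out$tukey <- tibble(
    comparison = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha)
  class(out) <- "interaction_group_test"
  out
}

#' @export
print.interaction_group_test <- function(x, ...) {
  if (x$skipped) {
    cat("<interaction_group_test> skipped: degenerate variance\n")
    return(invisible(x))
  }
  cat(sprintf("<interaction_group_test> %s by %s: ANOVA p = %.3g\n",
              x$metric, x$by, x$anova_p))
  print(x$tukey)
  invisible(x)
}

#' @rdname compare_interaction_groups
#' @param x An `interaction_group_test`.
#' @export
tidy.interaction_group_test <- function(x, ...) x$tukey

#' @rdname compare_interaction_groups
#' @export
glance.interaction_group_test <- function(x, ...) {
  tibble(by = x$by, metric = x$metric, anova_p = x$anova_p,
         skipped = x$skipped, alpha = x$alpha)
}

# deterministic heat-map ordering: miRNAs by (relevance group,) name;
# pathways blocked by canonical group order, then name
heatmap_orders <- function(nodes, relevance = NULL) {
  group_order <- c("Cancer", "Motility", "DNA Repair", "Cell Cycle",
                   "Apoptosis", "Miscellaneous", "Canonical")
  path_tab <- dplyr::distinct(nodes, .data$pathway, .data$group) %>%
    dplyr::mutate(g = factor(.data$group, levels = group_order)) %>%
    dplyr::arrange(.data$g, .data$pathway)
  mirnas <- sort(unique(nodes$mirna))
  if (!is.null(relevance)) {
    rel <- relevance[match(mirnas, relevance$mirna), "relevance_group",
                     drop = TRUE]
    mirnas <- mirnas[order(rel, mirnas)]
  }
  list(mirnas = mirnas, pathways = path_tab$pathway)
}

#' Export the three interaction heat-map matrices
#'
#' Writes one wide matrix per metric view — intersections (0/1), percent
#' overlap, and cumulative absolute FC — with miRNAs as rows (grouped by
#' GBM relevance when an annotation is supplied) and pathways as columns in
#' functional-group-blocked order. Ordering is deterministic, so re-export
#' of the same nodes is byte-identical.
#'
#' @param nodes An [score_interactions()] result.
#' @param dir Output directory (created if missing).
#' @param relevance Optional miRNA relevance annotation
#'   (`mirna`, `relevance_group`) used to order rows.
#' @param prefix File-name prefix (default "heatmap").
#' @return Named character vector of the three file paths, invisibly.
#' @export
export_heatmaps <- function(nodes, dir, relevance = NULL,
                            prefix = "heatmap") {
  stopifnot(inherits(nodes, "interaction_nodes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- heatmap_orders(nodes, relevance)
  metrics <- c(intersections = "intersects",
               percent_overlap = "percent_overlap",
               cumulative_abs_fc = "cumulative_abs_fc")
  paths <- purrr::imap_chr(metrics, function(col, nm) {
    wide <- nodes %>%
      dplyr::mutate(value = as.numeric(.data[[col]])) %>%
      dplyr::select("mirna", "pathway", "value") %>%
      tidyr::pivot_wider(names_from = "pathway", values_from = "value",
                         values_fill = 0)
    wide <- wide[match(ord$mirnas, wide$mirna),
                 c("mirna", intersect(ord$pathways, names(wide)))]
    f <- file.path(dir, sprintf("%s_%s.tsv", prefix, nm))
    readr::write_tsv(wide, f)
    f
  })
  invisible(paths)
}

#' Heat map of an interaction-node metric
#'
#' @param nodes An [score_interactions()] result.
#' @param metric Node column to display.
#' @param relevance Optional miRNA relevance annotation for row ordering.
#' @return A ggplot object (tiles: pathways x miRNAs, facetted by pathway
#'   group).
#' @export
plot_interaction_heatmap <- function(nodes,
                                     metric = c("percent_overlap",
                                                "cumulative_abs_fc",
                                                "intersects"),
                                     relevance = NULL) {
  stopifnot(inherits(nodes, "interaction_nodes"))
  metric <- match.arg(metric)
  ord <- heatmap_orders(nodes, relevance)
  df <- nodes %>%
    dplyr::mutate(
      mirna = factor(.data$mirna, levels = rev(ord$mirnas)),
      pathway = factor(.data$pathway, levels = ord$pathways),
      value = as.numeric(.data[[metric]]))
  ggplot(df, aes(x = .data$pathway, y = .data$mirna, fill = .data$value)) +
    geom_tile() +
    facet_grid(cols = dplyr::vars(.data$group), scales = "free_x",
               space = "free_x") +
    scale_fill_viridis_c(name = metric) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1, size = 7))
}

#' @rdname plot_interaction_heatmap
#' @param object An `interaction_nodes` tibble.
#' @param ... Passed to `plot_interaction_heatmap()`.
#' @export
autoplot.interaction_nodes <- function(object, ...) {
  plot_interaction_heatmap(object, ...)
}
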