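test_that("miRNA id substitutions map host genes and precursor variants", {
  expect_equal(as.character(apply_substitutions("mir-548-AJ2")),
               "hsa-mir-548aj")
  expect_equal(as.character(apply_substitutions("mir-181-A1-HG")),
               "hsa-mir-181a")
  expect_equal(as.character(apply_substitutions("mir-9999")), "mir-9999")
  expect_equal(as.character(apply_substitutions("MIR-548-aj2")),
               "hsa-mir-548aj")   # case-insensitive matching
  conflicting <- tibble::tibble(
    reported_id = c("a", "A"), substituted_id = c("x", "y"), reason = "host_gene")
  expect_error(apply_substitutions("a", conflicting),
               class = "mechanomir_config_error")
})

test_that("pathway classification is total, deterministic and rule-ordered", {
  expect_equal(classify_pathway("cell projection morphogenesis"), "Motility")
  expect_equal(classify_pathway("Apoptotic Process"), "Apoptosis")
  expect_equal(classify_pathway("zzz unmatched zzz"), "Miscellaneous")
  # exclusion: an ATM *signaling* network is canonical, not DNA repair
  expect_equal(classify_pathway("ATM Signaling Network in Development and Disease"),
               "Canonical")
  expect_equal(classify_pathway("ATM-dependent DNA damage response"),
               "DNA Repair")
  expect_equal(classify_pathway("Pathways in cancer"), "Cancer")
  expect_equal(classify_pathway("KEGG Glioma"), "Cancer")
  # stability: identical input, identical output
  nms <- c("wnt signaling", "dna repair", "mitotic spindle checkpoint", "x")
  expect_identical(classify_pathway(nms), classify_pathway(nms))
  expect_length(classify_pathway(character(0)), 0)
})

test_that("node scoring matches hand enumeration", {
  exports <- tibble::tibble(
    mirna = "mir-x", pathway = "wnt signaling", database = "KEGG",
    enrichment_p = 0.01, targets = list(c("A", "B", "C", "D")))
  de <- tibble::tibble(feature_id = c("A", "C"), fold_change = c(3.0, -2.5))
  node <- score_interactions(exports, de)
  expect_true(node$intersects)
  expect_equal(node$percent_overlap, 50)
  expect_equal(node$cumulative_abs_fc, 5.5)
  expect_equal(node$group, "Canonical")

  none <- score_interactions(exports,
                             tibble::tibble(feature_id = "Z", fold_change = 9))
  expect_equal(none$percent_overlap, 0)
  expect_equal(none$cumulative_abs_fc, 0)

  all_de <- score_interactions(
    exports, tibble::tibble(feature_id = c("A", "B", "C", "D"),
                            fold_change = c(2.1, -2.2, 3, 4)))
  expect_equal(all_de$percent_overlap, 100)

  bad <- dplyr::mutate(exports, targets = list(character(0)))
  expect_error(score_interactions(bad, de), class = "mechanomir_domain_error")
})

test_that("scoring equals the brute-force oracle on a full synthetic database", {
  es <- simulate_expression_set(150, 25, seed = 31)
  de <- filter_de(es$records)
  db <- simulate_pathway_db(sprintf("mir-%d", 1:4),
                            feature_ids = es$records$feature_id,
                            n_pathways_per_group = 1,
                            targets_per_pathway = 10,
                            prop_significant = 0.6, seed = 32)
  nodes <- score_interactions(db$exports, de)
  expect_equal(nrow(nodes), nrow(db$exports))   # no duplicate collapse needed
  de_fc <- setNames(de$fold_change, de$feature_id)
  for (i in seq_len(nrow(db$exports))) {
    row <- db$exports[i, ]
    o <- score_node_oracle(row$targets[[1]], names(de_fc), as.list(de_fc),
                           row$enrichment_p)
    hit <- nodes[nodes$mirna == row$mirna & nodes$pathway == row$pathway, ]
    expect_equal(hit$intersects, o$intersects)
    expect_equal(hit$n_de_targets, o$n_de_targets)
    expect_equal(hit$percent_overlap, o$percent_overlap)
    expect_equal(hit$cumulative_abs_fc, o$cumulative_abs_fc)
  }
  # upstream filter guarantees every DE target contributes |FC| > 2
  expect_true(all(nodes$cumulative_abs_fc >= 2 * nodes$n_de_targets))
  expect_true(all(nodes$percent_overlap >= 0 & nodes$percent_overlap <= 100))
  expect_equal(nodes$cumulative_abs_fc == 0, nodes$n_de_targets == 0)
})

test_that("duplicate export rows consolidate by union and minimum p", {
  exports <- tibble::tibble(
    mirna = "m", pathway = "dna repair",
    database = c("KEGG", "KEGG", "Reactome"),
    enrichment_p = c(0.04, 0.002, 0.2),
    targets = list(c("A", "B"), c("B", "C"), c("C", "D")))
  de <- tibble::tibble(feature_id = c("A", "D"), fold_change = c(3, -4))
  node <- score_interactions(exports, de)
  expect_equal(nrow(node), 1)
  expect_equal(node$n_targets, 4)        # union {A,B,C,D}
  expect_equal(node$enrichment_p, 0.002) # minimum across merges
  expect_equal(node$cumulative_abs_fc, 7)
})

test_that("intersection counts answer the pathways-hit-by-many-miRNAs query", {
  exports <- dplyr::mutate(
    tidyr::expand_grid(mirna = sprintf("m%d", 1:5),
                       pathway = "cell migration"),
    database = "GO-BP",
    enrichment_p = c(0.01, 0.2, 0.03, 0.04, 0.9),
    targets = list("A"))
  nodes <- score_interactions(exports,
                              tibble::tibble(feature_id = "A", fold_change = 3))
  expect_equal(count_intersections(nodes, "cell migration"), 3)
  tab <- count_intersections(nodes)
  expect_equal(tab$n_mirna_intersecting, 3)
  expect_error(count_intersections(nodes, "no such pathway"),
               class = "mechanomir_lookup_error")
})

test_that("aggregation averages all nodes including zeros", {
  exports <- tibble::tibble(
    mirna = c("m1", "m2"), pathway = "cell migration", database = "GO-BP",
    enrichment_p = 0.01, targets = list(c("A", "B"), c("C", "D")))
  de <- tibble::tibble(feature_id = c("A", "B"), fold_change = c(3, 4))
  nodes <- score_interactions(exports, de)
  agg <- aggregate_interactions(nodes, "pathway_group", "percent_overlap")
  expect_equal(agg$mean, 50)  # nodes at 100 and 0
  expect_equal(agg$n, 2)
  # invariance to node order
  agg2 <- aggregate_interactions(nodes[2:1, ], "pathway_group",
                                 "percent_overlap")
  expect_equal(agg2$mean, agg$mean)
  # relevance grouping requires the annotation
  expect_error(aggregate_interactions(nodes, "relevance_group"),
               class = "mechanomir_config_error")
  rel <- tibble::tibble(mirna = c("m1", "m2"),
                        relevance_group = c("GBM", "other"))
  aggr <- aggregate_interactions(nodes, "relevance_group",
                                 relevance = rel)
  expect_setequal(aggr$relevance_group, c("GBM", "other"))
})

test_that("construction can separate overlap-heavy from fold-change-heavy groups", {
  # Motility nodes: few DE targets but huge |FC|; Cancer nodes: many DE
  # targets with modest |FC| - the aggregate means must rank accordingly.
  de <- tibble::tibble(feature_id = c("big1", "big2", sprintf("mod%d", 1:8)),
                       fold_change = c(30, 28, rep(2.3, 8)))
  exports <- dplyr::bind_rows(
    dplyr::mutate(
      tidyr::expand_grid(mirna = sprintf("m%d", 1:3),
                         pathway = c("cell migration", "cell motility x")),
      database = "GO-BP", enrichment_p = 0.01,
      targets = list(c("big1", "big2", sprintf("non%d", 1:8)))),
    dplyr::mutate(
      tidyr::expand_grid(mirna = sprintf("m%d", 1:3),
                         pathway = c("glioma", "pathways in cancer")),
      database = "KEGG", enrichment_p = 0.01,
      targets = list(c(sprintf("mod%d", 1:8), "nonA", "nonB"))))
  nodes <- score_interactions(exports, de)
  fc <- aggregate_interactions(nodes, "pathway_group", "cumulative_abs_fc")
  ov <- aggregate_interactions(nodes, "pathway_group", "percent_overlap")
  expect_gt(fc$mean[fc$group == "Motility"], fc$mean[fc$group == "Cancer"])
  expect_lt(ov$mean[ov$group == "Motility"], ov$mean[ov$group == "Cancer"])
})

test_that("group comparison controls type-I error and detects real shifts", {
  # null: two relevance groups drawn from one distribution
  set.seed(55)
  n_sig <- 0
  for (i in 1:100) {
    vals <- rnorm(20, 10, 2)
    nodes <- structure(
      tibble::tibble(mirna = sprintf("m%d", 1:20),
                     pathway = "p", group = "Cancer",
                     relevance_group = rep(c("a", "b"), each = 10),
                     intersects = TRUE, n_targets = 10, n_de_targets = 1,
                     percent_overlap = vals, cumulative_abs_fc = vals),
      class = c("interaction_nodes", class(tibble::tibble())))
    res <- compare_interaction_groups(nodes, "relevance_group",
                                      "percent_overlap")
    n_sig <- n_sig + (res$anova_p < 0.05)
  }
  expect_lte(n_sig, 12)   # nominal 5%, binomial slack

  # strong separation is detected
  nodes2 <- structure(
    tibble::tibble(mirna = sprintf("m%d", 1:12), pathway = "p",
                   group = rep(c("Cancer", "Motility"), each = 6),
                   intersects = TRUE, n_targets = 1, n_de_targets = 1,
                   percent_overlap = c(rnorm(6, 0, 1), rnorm(6, 5, 1)),
                   cumulative_abs_fc = 1),
    class = c("interaction_nodes", class(tibble::tibble())))
  res2 <- compare_interaction_groups(nodes2, "pathway_group",
                                     "percent_overlap")
  expect_lt(res2$anova_p, 0.05)
  expect_true(all(tidy(res2)$significant))

  # three identical groups: omnibus and all pairwise non-significant
  nodes3 <- structure(
    tibble::tibble(mirna = sprintf("m%d", 1:12), pathway = "p",
                   group = rep(c("Cancer", "Motility", "Apoptosis"), 4),
                   intersects = TRUE, n_targets = 1, n_de_targets = 1,
                   percent_overlap = rep(c(1, 2, 3, 4), each = 3),
                   cumulative_abs_fc = 1),
    class = c("interaction_nodes", class(tibble::tibble())))
  res3 <- compare_interaction_groups(nodes3, "pathway_group",
                                     "percent_overlap")
  expect_false(any(tidy(res3)$significant))

  # degenerate variance is reported, not tested
  nodes4 <- dplyr::mutate(nodes3, percent_overlap = 1)
  class(nodes4) <- class(nodes3)
  expect_true(compare_interaction_groups(nodes4, "pathway_group",
                                         "percent_overlap")$skipped)
})

test_that("heat-map export is deterministic, complete and round-trips", {
  dir <- withr::local_tempdir()
  es <- simulate_expression_set(100, 15, seed = 61)
  db <- simulate_pathway_db(c("m1", "m2", "m3"),
                            feature_ids = es$records$feature_id,
                            n_pathways_per_group = 1, seed = 62)
  nodes <- score_interactions(db$exports, filter_de(es$records))
  paths <- export_heatmaps(nodes, dir)
  expect_length(paths, 3)
  for (p in paths) {
    m <- readr::read_tsv(p, show_col_types = FALSE)
    expect_equal(dim(m), c(3, 8))   # 3 miRNAs x (id col + 7 pathways)
  }
  ov <- readr::read_tsv(paths[["percent_overlap"]], show_col_types = FALSE)
  for (i in seq_len(nrow(nodes))) {
    expect_equal(ov[[nodes$pathway[i]]][ov$mirna == nodes$mirna[i]],
                 nodes$percent_overlap[i])
  }
  # re-export byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- export_heatmaps(nodes, dir2)
  for (k in names(paths)) {
    expect_identical(readLines(paths[[k]]), readLines(paths2[[k]]))
  }
  # empty DE: overlap and cumulative FC views are all zero
  nodes0 <- score_interactions(db$exports,
                               tibble::tibble(feature_id = character(0),
                                              fold_change = numeric(0)))
  d0 <- withr::local_tempdir()
  p0 <- export_heatmaps(nodes0, d0)
  z <- readr::read_tsv(p0[["cumulative_abs_fc"]], show_col_types = FALSE)
  expect_true(all(as.matrix(z[, -1]) == 0))
  expect_s3_class(plot_interaction_heatmap(nodes), "ggplot")
})
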