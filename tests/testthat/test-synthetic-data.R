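test_that("preset registry is complete and internally consistent", {
  pres <- condition_presets()
  expect_equal(nrow(pres), 10)
  expect_equal(anyDuplicated(pres$name), 0)
  expect_true(all(pres$wound_closure_ctrl >= 0 & pres$wound_closure_ctrl <= 1))
  expect_true(all(pres$wound_closure_exp >= 0 & pres$wound_closure_exp <= 1))
  expect_true(all(pres$elongated_fraction >= 0 & pres$elongated_fraction <= 1))
  for (i in seq_len(nrow(pres))) {
    mix <- pres$mixture[[i]]
    expect_equal(sum(mix$weights), 1, tolerance = 1e-6)
    expect_true(all(mix$modes >= 1))
    if (length(mix$modes) == 2) expect_gt(mix$modes[2], mix$modes[1])
    # stored mu must invert the mode formula exactly
    expect_equal(component_mode(mix$mus, mix$sigmas), mix$modes,
                 tolerance = 1e-10)
    # stored elongated fraction equals the mixture-implied P(AR >= 2)
    implied <- sum(mix$weights * pnorm(mix$mus / mix$sigmas))
    expect_equal(pres$elongated_fraction[i], implied, tolerance = 1e-3)
  }
})

test_that("aspect-ratio samples respect the mixture and the AR > 1 floor", {
  expect_error(simulate_aspect_ratios("no-such-preset", 10),
               class = "mechanomir_lookup_error")
  # degenerate component: sigma -> 0 collapses every draw onto the mode
  degenerate <- tibble::tibble(
    name = "point", cell_line = "x", pressure_pa = 0,
    wound_closure_ctrl = 0.5, wound_closure_exp = 0.5,
    elongated_fraction = 1,
    mixture = list(list(weights = 1, mus = 0, sigmas = 1e-8,
                        modes = 2)))
  ar <- simulate_aspect_ratios(degenerate, n = 5, seed = 1)
  expect_equal(ar$ar, rep(2, 5), tolerance = 1e-6)

  pres <- condition_presets()
  for (p in c("LN229-23Pa", "U251-Control", "LN229-115Pa")) {
    smp <- simulate_aspect_ratios(p, n = 1e4, seed = 3)
    expect_gt(min(smp$ar), 1)
    row <- pres[pres$name == p, ]
    d <- ks_distance(smp$ar, function(t) preset_cdf(row, t))
    expect_lt(d, 0.03)
  }
  # reproducibility
  expect_identical(simulate_aspect_ratios("LN229-23Pa", 100, seed = 9),
                   simulate_aspect_ratios("LN229-23Pa", 100, seed = 9))
})

test_that("wound pairs encode the requested closure exactly in truth areas", {
  expect_error(simulate_wound_pair(closure = 1.2), class = "mechanomir_domain_error")
  expect_error(simulate_wound_pair(gap_width = 0, closure = 0.5),
               class = "mechanomir_domain_error")
  sz <- c(250L, 250L)
  wp0 <- simulate_wound_pair(gap_width = 200, closure = 0, image_size = sz, seed = 1)
  expect_equal(wp0$true_area_final, wp0$true_area_initial)
  wp1 <- simulate_wound_pair(gap_width = 200, closure = 1, image_size = sz, seed = 1)
  expect_equal(wp1$true_area_final, 0)
  wp <- simulate_wound_pair(gap_width = 300, closure = 0.570,
                            image_size = c(400L, 400L), seed = 2)
  expect_identical(dim(wp$image_initial), dim(wp$image_final))
  expect_lte(wp$true_area_final, wp$true_area_initial)
  gap_px <- round(300 / wp$pixel_size)
  expect_lte(abs(wp$true_area_final / wp$true_area_initial - 0.430),
             1 / gap_px)   # +/- 1 px of band-width rounding
})

test_that("wound pairs round-trip through TIFF plus sidecar", {
  dir <- withr::local_tempdir()
  wp <- simulate_wound_pair(gap_width = 150, closure = 0.4,
                            image_size = c(120L, 120L), seed = 5)
  sc <- write_wound_pair(wp, dir, stem = "w1")
  back <- read_wound_pair(sc)
  expect_equal(back$true_area_initial, wp$true_area_initial)
  expect_equal(back$true_area_final, wp$true_area_final)
  # 16-bit quantisation only
  expect_lt(max(abs(back$image_initial - wp$image_initial)), 1 / 65535 + 1e-9)
})

test_that("expression sets contain exactly n_de filter-passing records", {
  es0 <- simulate_expression_set(100, 0, seed = 1)
  expect_equal(nrow(filter_de(es0$records)), 0)

  es <- simulate_expression_set(200, 30, seed = 7)
  expect_equal(anyDuplicated(es$records$feature_id), 0)
  expect_length(es$truth_de_ids, 30)
  # independent brute-force re-scan of the emitted table
  r <- es$records
  pass <- r$p_value < 0.05 & r$fdr < 0.05 & abs(r$fold_change) > 2
  expect_equal(sum(pass), 30)
  expect_setequal(r$feature_id[pass], es$truth_de_ids)
  expect_error(simulate_expression_set(10, 20), class = "mechanomir_domain_error")
  expect_error(simulate_expression_set(10, 2, fc_range = c(1.5, 3)),
               class = "mechanomir_domain_error")
})

test_that("pathway databases round-trip their truth groups through the classifier", {
  expect_error(simulate_pathway_db(character(0), feature_ids = letters),
               class = "mechanomir_domain_error")
  db <- simulate_pathway_db("mir-1", feature_ids = sprintf("G%02d", 1:30),
                            n_pathways_per_group = 1, seed = 1)
  expect_equal(nrow(db$truth_groups), 7)
  expect_equal(classify_pathway(db$truth_groups$pathway),
               db$truth_groups$group)
  # larger registry still classifies perfectly
  db2 <- simulate_pathway_db(c("mir-1", "mir-2"),
                             feature_ids = sprintf("G%02d", 1:30),
                             n_pathways_per_group = 6, seed = 2)
  expect_equal(classify_pathway(db2$truth_groups$pathway),
               db2$truth_groups$group)
  # node count is n_mirnas x n_pathways
  db3 <- simulate_pathway_db(c("a", "b", "c"),
                             feature_ids = sprintf("G%02d", 1:30),
                             n_pathways_per_group = 2, groups = "Motility",
                             seed = 3)
  expect_equal(nrow(db3$exports), 6)
  expect_true(all(db3$exports$enrichment_p < 0.05))
})
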