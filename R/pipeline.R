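#' Default pipeline configuration
#'
#' A plain named list; override any entry via the `...` of
#' [run_pipeline()] or by editing the list. Thresholds mirror the analysis
#' defaults: DE triple filter (p < 0.05, FDR < 0.05, |FC| > 2), AR
#' elongation threshold 2, Bonferroni-adjusted paired-test alpha 0.01, and
#' group-comparison alpha 0.05.
#'
#' @param preset Condition preset name driving the generators.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory.
#' @return A named list.
#' @export
pipeline_config <- function(preset = "LN229-23Pa", seed = 42L,
                            out_dir = tempfile("mechanomir_run_")) {
  list(
    preset = preset, seed = as.integer(seed), out_dir = out_dir,
    stages = c("simulate", "wound", "morpho", "filter", "interact"),
    n_replicates = 4L, image_size = c(400L, 400L), gap_width = 300,
    closure_sd = 0.03,
    n_cells = 2000L, bin_width = 0.1, ar_threshold = 2,
    n_features = 400L, n_de = 60L,
    n_pathways_per_group = 2L, targets_per_pathway = 8L,
    p_max = 0.05, fdr_max = 0.05, abs_fc_min = 2,
    alpha_paired = 0.01, alpha_groups = 0.05)
}

validate_config <- function(config) {
  base <- pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "mechanomir_config_error")
  }
  config <- utils::modifyList(base, config)
  bad_stage <- setdiff(config$stages, base$stages)
  if (length(bad_stage) > 0) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad_stage, collapse = ", ")),
          class = "mechanomir_config_error")
  }
  for (f in c("n_replicates", "n_cells", "n_features", "n_de")) {
    stopifnot_scalar_number(config[[f]], f, lower = 0)
  }
  config
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates the stages in dependency order — simulate (generators),
#' wound (segment, closure, paired differential closure), morpho (aspect
#' ratios, percent elongated, mixture fit and selection), filter (DE triple
#' filter and type split), interact (node scoring, group aggregation,
#' heat-map export) — writing every table under `out_dir` with a
#' provenance header (package version, seed, config hash). Idempotent: a
#' fixed config and seed reproduce every output byte-identically. Later
#' stages consume the in-run outputs of earlier ones, so requesting e.g.
#' `filter` without `simulate` is a configuration error.
#'
#' @param config A [pipeline_config()] list (entries may be overridden via
#'   `...`).
#' @param ... Individual config overrides, e.g. `preset = "U251-23Pa"`.
#' @return A run manifest tibble (`stage`, `output`, `path`), invisibly
#'   also written to `manifest.tsv`.
#' @examples
#' \donttest{
#' man <- run_pipeline(pipeline_config(out_dir = tempfile()))
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), ...) {
  config <- utils::modifyList(config, list(...))
  config <- validate_config(config)
  needs_sim <- c("wound", "morpho", "filter", "interact")
  if (any(needs_sim %in% config$stages) && !"simulate" %in% config$stages) {
    abort("Stages depending on synthetic inputs require the `simulate` stage (field: stages).",
          class = "mechanomir_config_error")
  }
  if ("interact" %in% config$stages && !"filter" %in% config$stages) {
    abort("Stage `interact` consumes the DE split and requires `filter` (field: stages).",
          class = "mechanomir_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration only, not where it is written
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  seed <- config$seed
  preset <- get_preset(config$preset)
  manifest <- list()
  note <- function(stage, output, path) {
    manifest[[length(manifest) + 1]] <<- tibble(stage = stage,
                                                output = output, path = path)
  }
  wtsv <- function(x, name, stage) {
    p <- file.path(config$out_dir, name)
    write_tsv_provenance(x, p, seed = seed, config_hash = hash)
    note(stage, sub("[.]tsv$", "", name), p)
    p
  }

  sim <- NULL
  if ("simulate" %in% config$stages) {
    # per-replicate closures jitter around the preset values (clamped to [0,1])
    jit <- withr::with_seed(seed, matrix(
      stats::rnorm(2 * config$n_replicates, 0, config$closure_sd), ncol = 2))
    closures <- tibble(
      replicate_id = sprintf("rep%02d", seq_len(config$n_replicates)),
      closure_ctrl = pmin(1, pmax(0, preset$wound_closure_ctrl + jit[, 1])),
      closure_exp = pmin(1, pmax(0, preset$wound_closure_exp + jit[, 2])))
    pairs <- purrr::pmap(closures, function(replicate_id, closure_ctrl,
                                            closure_exp) {
      list(ctrl = simulate_wound_pair(config$gap_width, closure_ctrl,
                                      image_size = config$image_size,
                                      seed = seed + 31L * match(replicate_id, closures$replicate_id)),
           exp = simulate_wound_pair(config$gap_width, closure_exp,
                                     image_size = config$image_size,
                                     seed = seed + 63L * match(replicate_id, closures$replicate_id)))
    })
    ar <- simulate_aspect_ratios(preset, n = config$n_cells, seed = seed + 7L)
    es <- simulate_expression_set(config$n_features, config$n_de,
                                  seed = seed + 11L)
    sim <- list(closures = closures, pairs = pairs, ar = ar, es = es)
    wtsv(closures, "simulated_closures.tsv", "simulate")
    wtsv(es$records, "expression.tsv", "simulate")
  }

  if ("wound" %in% config$stages) {
    areas <- purrr::imap(sim$pairs, function(pr, i) {
      dplyr::bind_rows(
        tibble(condition = "control",
               replicate_id = sim$closures$replicate_id[i],
               area_initial = segment_cell_free_area(pr$ctrl$image_initial),
               area_final = segment_cell_free_area(pr$ctrl$image_final)),
        tibble(condition = preset$name,
               replicate_id = sim$closures$replicate_id[i],
               area_initial = segment_cell_free_area(pr$exp$image_initial),
               area_final = segment_cell_free_area(pr$exp$image_final)))
    }) %>% dplyr::bind_rows()
    wc <- wound_closure(areas)
    dc <- differential_closure(
      pair_closures(wc, condition = preset$name, control = "control"),
      alpha = config$alpha_paired)
    dc$fold_increase <- fold_increase(
      mean(wc$wc[wc$condition == "control"]), dc$delta_wc_mean)
    wtsv(wc, "wound_closure.tsv", "wound")
    wtsv(dc, "differential_closure.tsv", "wound")
  }

  if ("morpho" %in% config$stages) {
    fit <- fit_ar_mixture(sim$ar, bin_width = config$bin_width)
    morpho <- dplyr::bind_cols(
      tibble(condition = preset$name,
             percent_elongated = percent_elongated(sim$ar,
                                                   config$ar_threshold),
             relevant_secondary = flag_relevant_secondary(fit,
                                                          config$ar_threshold)),
      glance(fit))
    wtsv(morpho, "morphometrics.tsv", "morpho")
    wtsv(tidy(fit), "mixture_components.tsv", "morpho")
  }

  de_split <- NULL
  if ("filter" %in% config$stages) {
    de <- filter_de(sim$es$records, p_max = config$p_max,
                    fdr_max = config$fdr_max, abs_fc_min = config$abs_fc_min)
    de_split <- split_by_type(de)
    wtsv(de, "de_filtered.tsv", "filter")
  }

  if ("interact" %in% config$stages) {
    mirnas <- de_split$precursor_mirna$feature_id
    if (length(mirnas) == 0) {
      abort("No precursor miRNAs survived the filter; cannot run `interact`.",
            class = "mechanomir_data_error")
    }
    db <- simulate_pathway_db(
      mirnas, feature_ids = sim$es$records$feature_id,
      n_pathways_per_group = config$n_pathways_per_group,
      targets_per_pathway = config$targets_per_pathway, seed = seed + 13L)
    nodes <- score_interactions(db$exports, de_split$coding,
                                alpha = config$alpha_groups)
    agg <- dplyr::bind_rows(
      aggregate_interactions(nodes, "pathway_group", "percent_overlap"),
      aggregate_interactions(nodes, "pathway_group", "cumulative_abs_fc"))
    hm <- export_heatmaps(nodes, config$out_dir)
    wtsv(as_tibble(nodes), "interaction_nodes.tsv", "interact")
    wtsv(agg, "interaction_group_means.tsv", "interact")
    for (nm in names(hm)) note("interact", paste0("heatmap_", nm), hm[[nm]])
  }

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  manifest
}
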