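#' Segment the cell-free area of a wound-assay image
#'
#' Global Otsu threshold on intensity, morphological closing with a 3-pixel
#' disc to heal speckle, connected-component labelling, and selection of the
#' largest dark (cell-free) region. Deterministic for a fixed input; the
#' choice of segmentation recipe is isolated behind this one function so
#' alternatives can be swapped in.
#'
#' @param image Numeric 2-D grayscale matrix (any positive range; rescaled
#'   to `[0, 1]` internally).
#' @param pixel_size Micrometres per pixel (default 1, i.e. area in px^2).
#' @return The area of the largest cell-free region, in `pixel_size^2`
#'   units.
#' @examples
#' wp <- simulate_wound_pair(closure = 0.5, image_size = c(200, 200), seed = 1)
#' segment_cell_free_area(wp$image_initial)
#' @export
segment_cell_free_area <- function(image, pixel_size = 1) {
  if (!is.matrix(image) || length(image) == 0) {
    abort("`image` must be a non-empty 2-D matrix.",
          class = "mechanomir_domain_error")
  }
  rng <- range(image, finite = TRUE)
  if (diff(rng) == 0) {
    abort("Uniform image: no threshold separates cell-free from cells.",
          class = "mechanomir_degenerate_input")
  }
  img <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(img))
  dark <- EBImage::Image(img < thr)
  dark <- EBImage::closing(dark, EBImage::makeBrush(3, shape = "disc"))
  labels <- EBImage::bwlabel(dark)
  sizes <- tabulate(as.integer(EBImage::imageData(labels)))
  if (length(sizes) == 0) {
    abort("No cell-free region found below the Otsu threshold.",
          class = "mechanomir_degenerate_input")
  }
  max(sizes) * pixel_size^2
}

#' Wound closure from initial and final cell-free areas
#'
#' `WC = (area_initial - area_final) / area_initial`: the fraction of the
#' original gap closed over the assay. Scale-invariant, 0 when the areas are
#' equal and 1 when the gap closes completely.
#'
#' @param areas A data frame with columns `area_initial` (> 0) and
#'   `area_final` (same units), plus any id columns (e.g. `condition`,
#'   `replicate_id`) which are carried through.
#' @return The input tibble with a `wc` column appended.
#' @examples
#' wound_closure(tibble::tibble(area_initial = 100, area_final = 43))$wc
#' @export
wound_closure <- function(areas) {
  need <- c("area_initial", "area_final")
  if (!is.data.frame(areas) || !all(need %in% names(areas))) {
    abort("`areas` needs columns `area_initial` and `area_final`.",
          class = "mechanomir_schema_error")
  }
  if (any(areas$area_initial <= 0)) {
    abort("`area_initial` must be > 0.", class = "mechanomir_domain_error")
  }
  dplyr::mutate(as_tibble(areas),
                wc = (.data$area_initial - .data$area_final) / .data$area_initial)
}

#' Pair per-replicate closures of a condition with its same-day control
#'
#' Wound-healing runs are matched-pair experiments: each replicate of a
#' compression condition is paired with the control run the same day.
#' Pairing is by explicit `replicate_id`, never by row order.
#'
#' @param closures A data frame with `condition`, `replicate_id`, `wc`.
#' @param condition Label of the experimental condition.
#' @param control Label of the control condition.
#' @return A tibble with `replicate_id`, `wc_exp`, `wc_ctrl` (inner join on
#'   `replicate_id`).
#' @export
pair_closures <- function(closures, condition, control) {
  need <- c("condition", "replicate_id", "wc")
  if (!all(need %in% names(closures))) {
    abort("`closures` needs columns condition, replicate_id, wc.",
          class = "mechanomir_schema_error")
  }
  exp <- dplyr::filter(closures, .data$condition == !!condition)
  ctl <- dplyr::filter(closures, .data$condition == !!control)
  dplyr::inner_join(
    dplyr::select(exp, "replicate_id", wc_exp = "wc"),
    dplyr::select(ctl, "replicate_id", wc_ctrl = "wc"),
    by = "replicate_id")
}

#' Differential wound closure of matched pairs
#'
#' The mean matched-pair difference `mean(wc_exp - wc_ctrl)` in percentage
#' points, with its SEM and a one-sided paired t-test (alternative: closure
#' greater than control). Significance is flagged at a Bonferroni-adjusted
#' level, `alpha = 0.05 / 5 = 0.01` by default for the five
#' condition-vs-control comparisons of a pressure series. The test runs on
#' the raw paired differences. With a single pair or zero-variance
#' differences no test is possible and `p_value` is `NA` (flagged not
#' significant).
#'
#' @param pairs A data frame with columns `wc_exp` and `wc_ctrl`
#'   (fractions), one row per matched replicate pair.
#' @param alpha Significance level after multiplicity adjustment
#'   (default 0.01).
#' @return A one-row tibble: `delta_wc_mean` and `delta_wc_sem` (percentage
#'   points), `n_pairs`, `p_value`, `significant`, `alpha`.
#' @examples
#' differential_closure(tibble::tibble(
#'   wc_exp = c(0.80, 0.82, 0.79), wc_ctrl = c(0.57, 0.58, 0.55)))
#' @export
differential_closure <- function(pairs, alpha = 0.01) {
  need <- c("wc_exp", "wc_ctrl")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs)) ||
      nrow(pairs) == 0) {
    abort("`pairs` needs >= 1 row with columns `wc_exp` and `wc_ctrl`.",
          class = "mechanomir_domain_error")
  }
  d_pp <- 100 * (pairs$wc_exp - pairs$wc_ctrl)
  p <- if (length(d_pp) >= 2 && stats::sd(d_pp) > 0) {
    stats::t.test(d_pp, alternative = "greater")$p.value
  } else {
    NA_real_
  }
  tibble(
    delta_wc_mean = mean(d_pp), delta_wc_sem = sem(d_pp),
    n_pairs = length(d_pp), p_value = p,
    significant = !is.na(p) && p < alpha, alpha = alpha)
}

#' Fold increase in wound closure implied by a differential closure
#'
#' Converts a control closure (fraction) and a differential closure
#' (percentage points) into the fold change of gap closed:
#' `(100 * wc_ctrl + delta_wc) / (100 * wc_ctrl)`.
#'
#' @param wc_ctrl Control wound closure as a fraction (> 0).
#' @param delta_wc Differential closure in percentage points.
#' @return The fold increase (1 when `delta_wc = 0`).
#' @examples
#' fold_increase(0.570, 23.2)  # ~1.41
#' @export
fold_increase <- function(wc_ctrl, delta_wc) {
  if (any(wc_ctrl <= 0)) {
    abort("`wc_ctrl` must be > 0.", class = "mechanomir_domain_error")
  }
  (100 * wc_ctrl + delta_wc) / (100 * wc_ctrl)
}
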