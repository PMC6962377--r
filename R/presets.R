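#' Condition presets for the synthetic-data generators
#'
#' The registry of experimental conditions (cell line x applied pressure)
#' that drives every synthetic generator. Each preset carries the wound
#' closure of the condition and its matched control (fractions of the initial
#' gap), the fraction of elongated cells (aspect ratio >= 2), and a one- or
#' two-component shifted-lognormal mixture describing the aspect-ratio
#' distribution. Mixture components are stored as (weight, mode, sigma)
#' triples; the log-location `mu` of each component is derived by inverting
#' the mode formula, `mu = log(mode - 1) + sigma^2`, so that presets are
#' exactly consistent with their stated peak locations.
#'
#' Ten presets ship with the package (five per cell line: Control, Agar,
#' 23 Pa, 47 Pa, 115 Pa), read from a versioned JSON file under
#' `inst/extdata/`. Users may point `file` at their own registry with the
#' same schema.
#'
#' @param file Path to a preset registry JSON file. Defaults to the registry
#'   shipped with the package.
#' @return A tibble with one row per preset: `name`, `cell_line`,
#'   `pressure_pa`, `wound_closure_ctrl`, `wound_closure_exp`,
#'   `elongated_fraction`, and a `mixture` list-column, each element a list
#'   with numeric `weights`, `modes`, `mus`, `sigmas`.
#' @examples
#' condition_presets()
#' @export
condition_presets <- function(file = NULL) {
  file <- file %||% system.file("extdata", "presets.json",
                                package = "mechanomir", mustWork = TRUE)
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  rows <- purrr::map(raw, function(p) {
    mix <- p$mixture
    mix <- list(
      weights = as.numeric(unlist(mix$weights)),
      modes   = as.numeric(unlist(mix$modes)),
      sigmas  = as.numeric(unlist(mix$sigmas))
    )
    mix$mus <- log(mix$modes - 1) + mix$sigmas^2
    validate_mixture_spec(mix, p$name)
    tibble(
      name = p$name, cell_line = p$cell_line,
      pressure_pa = as.numeric(p$pressure_pa),
      wound_closure_ctrl = as.numeric(p$wound_closure_ctrl),
      wound_closure_exp = as.numeric(p$wound_closure_exp),
      elongated_fraction = as.numeric(p$elongated_fraction),
      mixture = list(mix)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) {
    abort("Preset names must be unique within a registry.",
          class = "mechanomir_config_error")
  }
  bad <- out %>%
    dplyr::filter(.data$pressure_pa < 0 |
                  .data$wound_closure_ctrl < 0 | .data$wound_closure_ctrl > 1 |
                  .data$wound_closure_exp < 0 | .data$wound_closure_exp > 1 |
                  .data$elongated_fraction < 0 | .data$elongated_fraction > 1)
  if (nrow(bad) > 0) {
    abort(sprintf("Preset '%s' has out-of-range fields.", bad$name[1]),
          class = "mechanomir_config_error")
  }
  out
}

validate_mixture_spec <- function(mix, name = "<mixture>") {
  k <- length(mix$weights)
  if (k < 1 || k > 2 ||
      length(mix$modes) != k || length(mix$sigmas) != k) {
    abort(sprintf("Preset '%s': mixture must have 1 or 2 components.", name),
          class = "mechanomir_config_error")
  }
  if (any(mix$weights < 0) || abs(sum(mix$weights) - 1) > 1e-6) {
    abort(sprintf("Preset '%s': weights must be non-negative and sum to 1.", name),
          class = "mechanomir_config_error")
  }
  if (any(mix$sigmas <= 0)) {
    abort(sprintf("Preset '%s': sigmas must be > 0.", name),
          class = "mechanomir_config_error")
  }
  if (any(mix$modes < 1)) {
    abort(sprintf("Preset '%s': modes must be >= 1.", name),
          class = "mechanomir_config_error")
  }
  if (k == 2 && mix$modes[2] <= mix$modes[1]) {
    abort(sprintf("Preset '%s': mode2 must exceed mode1.", name),
          class = "mechanomir_config_error")
  }
  invisible(mix)
}

# look one preset up by name, accepting either a name or a presets row
get_preset <- function(preset, registry = NULL) {
  if (is.character(preset)) {
    registry <- registry %||% condition_presets()
    hit <- registry[registry$name == preset, ]
    if (nrow(hit) != 1) {
      abort(sprintf("Unknown preset '%s'. Available: %s.", preset,
                    paste(registry$name, collapse = ", ")),
            class = "mechanomir_lookup_error")
    }
    return(hit)
  }
  if (is.data.frame(preset) && nrow(preset) == 1 && "mixture" %in% names(preset)) {
    return(preset)
  }
  abort("`preset` must be a preset name or a single registry row.",
        class = "mechanomir_lookup_error")
}
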