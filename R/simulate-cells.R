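#' Draw a synthetic sample of single-cell aspect ratios
#'
#' Samples aspect ratios from a preset's shifted-lognormal mixture: a
#' component is selected with the mixture weights and `AR = 1 + x` with
#' `x ~ lognormal(mu, sigma)`, so every value exceeds 1 (AR = 1 is a perfect
#' circle and cannot be undercut).
#'
#' @param preset A preset name (see [condition_presets()]) or a single
#'   registry row.
#' @param n Number of cells to draw (>= 1).
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return A tibble with columns `cell_id`, `ar`, and `excluded` (always
#'   `"none"`; the column mirrors measured shape tables so synthetic samples
#'   flow through the same downstream functions).
#' @examples
#' ar <- simulate_aspect_ratios("LN229-23Pa", n = 500, seed = 1)
#' percent_elongated(ar)
#' @export
simulate_aspect_ratios <- function(preset, n, seed = 42L) {
  stopifnot_scalar_number(n, "n", lower = 1)
  preset <- get_preset(preset)
  mix <- preset$mixture[[1]]
  withr::with_seed(seed, {
    comp <- sample.int(length(mix$weights), size = n, replace = TRUE,
                       prob = mix$weights)
    x <- stats::rlnorm(n, meanlog = mix$mus[comp], sdlog = mix$sigmas[comp])
  })
  tibble(cell_id = sprintf("cell_%05d", seq_len(n)), ar = 1 + x,
         excluded = "none")
}

#' Generate a synthetic wound-assay image pair
#'
#' Emulates a pair of fluorescence images of a scratch/gap assay: a bright
#' speckled cell lawn with a dark vertical cell-free band of width
#' `gap_width` at time zero, and the same field with the band shrunk so that
#' its area is `(1 - closure)` times the initial band area (exact in pixels
#' up to rounding). True band areas are recorded so segmentation accuracy can
#' be scored against ground truth.
#'
#' @param gap_width Initial gap width in micrometres (> 0).
#' @param closure Fraction of the gap closed at the final time point, in
#'   `[0, 1]`.
#' @param pixel_size Micrometres per pixel. Default 1.61 (4x objective class).
#' @param image_size Integer `c(rows, cols)` of the images.
#' @param seed Integer seed for the speckle texture.
#' @return An object of class `wound_pair`: a list with `image_initial`,
#'   `image_final` (numeric matrices in `[0, 1]`), `true_area_initial`,
#'   `true_area_final` (pixel^2), `pixel_size`, `gap_width`, `closure`.
#' @examples
#' wp <- simulate_wound_pair(gap_width = 500, closure = 0.57, seed = 1)
#' wp$true_area_final / wp$true_area_initial
#' @export
simulate_wound_pair <- function(gap_width = 500, closure,
                                pixel_size = 1.61,
                                image_size = c(1000L, 1000L),
                                seed = 42L) {
  stopifnot_scalar_number(gap_width, "gap_width", lower = .Machine$double.eps)
  stopifnot_scalar_number(closure, "closure", lower = 0, upper = 1)
  nr <- as.integer(image_size[1]); nc <- as.integer(image_size[2])
  gap_px <- round(gap_width / pixel_size)
  if (gap_px < 2 || gap_px >= nc) {
    abort("Gap width must span at least 2 and fewer than ncol pixels.",
          class = "mechanomir_domain_error")
  }
  final_px <- round((1 - closure) * gap_px)

  band_cols <- function(width_px) {
    if (width_px == 0) return(integer(0))
    start <- floor((nc - width_px) / 2) + 1L
    seq.int(start, start + width_px - 1L)
  }
  paint <- function(width_px) {
    img <- matrix(stats::runif(nr * nc, 0.45, 1.0), nr, nc)
    cols <- band_cols(width_px)
    if (length(cols) > 0) {
      img[, cols] <- stats::runif(nr * length(cols), 0, 0.08)
      # sparse bright debris inside the gap; removed by morphological cleanup
      n_spk <- max(1L, round(0.002 * nr * length(cols)))
      idx <- cbind(sample.int(nr, n_spk, replace = TRUE),
                   sample(cols, n_spk, replace = TRUE))
      img[idx] <- stats::runif(n_spk, 0.7, 1.0)
    }
    # sparse dark pixels in the lawn (gaps between cells)
    n_drk <- round(0.002 * nr * nc)
    idx <- cbind(sample.int(nr, n_drk, replace = TRUE),
                 sample.int(nc, n_drk, replace = TRUE))
    keep <- !(idx[, 2] %in% cols)
    img[idx[keep, , drop = FALSE]] <- stats::runif(sum(keep), 0, 0.08)
    img
  }
  withr::with_seed(seed, {
    image_initial <- paint(gap_px)
    image_final <- paint(final_px)
  })
  structure(
    list(image_initial = image_initial, image_final = image_final,
         true_area_initial = gap_px * nr, true_area_final = final_px * nr,
         pixel_size = pixel_size, gap_width = gap_width, closure = closure),
    class = "wound_pair"
  )
}

#' @export
print.wound_pair <- function(x, ...) {
  cat(sprintf(
    "<wound_pair> %d x %d px, %.2f um/px, gap %.0f um, closure %.3f\n",
    nrow(x$image_initial), ncol(x$image_initial), x$pixel_size,
    x$gap_width, x$closure))
  cat(sprintf("  true areas: %d -> %d px^2\n",
              x$true_area_initial, x$true_area_final))
  invisible(x)
}

#' Write / read a wound pair as TIFF images plus a truth sidecar
#'
#' `write_wound_pair()` stores the two grayscale images as TIFF files and the
#' generator's true areas in a tab-separated sidecar; `read_wound_pair()`
#' reconstructs the object.
#'
#' @param pair A [simulate_wound_pair()] object.
#' @param dir Directory to write into (created if missing).
#' @param stem File name stem.
#' @return `write_wound_pair()` returns the sidecar path invisibly;
#'   `read_wound_pair()` returns a `wound_pair`.
#' @export
write_wound_pair <- function(pair, dir, stem = "wound") {
  stopifnot(inherits(pair, "wound_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f0 <- file.path(dir, paste0(stem, "_initial.tif"))
  f1 <- file.path(dir, paste0(stem, "_final.tif"))
  EBImage::writeImage(EBImage::Image(pair$image_initial), f0, type = "tiff",
                      bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(pair$image_final), f1, type = "tiff",
                      bits.per.sample = 16L)
  sidecar <- file.path(dir, paste0(stem, "_truth.tsv"))
  readr::write_tsv(tibble(
    image_initial = basename(f0), image_final = basename(f1),
    true_area_initial = pair$true_area_initial,
    true_area_final = pair$true_area_final,
    pixel_size = pair$pixel_size, gap_width = pair$gap_width,
    closure = pair$closure), sidecar)
  invisible(sidecar)
}

#' @rdname write_wound_pair
#' @param sidecar Path to a `*_truth.tsv` sidecar written by
#'   `write_wound_pair()`.
#' @export
read_wound_pair <- function(sidecar) {
  meta <- readr::read_tsv(sidecar, show_col_types = FALSE)
  dir <- dirname(sidecar)
  img <- function(f) {
    as.matrix(EBImage::imageData(EBImage::readImage(file.path(dir, f))))
  }
  structure(
    list(image_initial = img(meta$image_initial),
         image_final = img(meta$image_final),
         true_area_initial = meta$true_area_initial,
         true_area_final = meta$true_area_final,
         pixel_size = meta$pixel_size, gap_width = meta$gap_width,
         closure = meta$closure),
    class = "wound_pair")
}
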