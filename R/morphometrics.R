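#' Measure single-cell shape from a labeled mask
#'
#' Computes, per labeled object, the aspect ratio (major/minor axis of the
#' best-fit, moment-equivalent ellipse) and area. Objects touching the image
#' border are flagged `excluded = "edge"` and never enter downstream
#' statistics; dividing cells cannot be recognised from a mask alone and are
#' accepted as a pre-set `"dividing"` flag in tabular inputs instead.
#'
#' @param label_mask Integer-labeled matrix; background is 0.
#' @param pixel_size Micrometres per pixel (default 1, i.e. areas in px^2).
#' @return A tibble with `label`, `ar`, `area`, `excluded`
#'   (`"none"`/`"edge"`). Empty mask gives an empty tibble.
#' @examples
#' m <- matrix(0L, 60, 60); m[10:49, 20:29] <- 1L
#' measure_shapes(m)
#' @export
measure_shapes <- function(label_mask, pixel_size = 1) {
  if (!is.matrix(label_mask)) {
    abort("`label_mask` must be a matrix.", class = "mechanomir_domain_error")
  }
  labs <- sort(setdiff(unique(as.vector(label_mask)), 0))
  if (length(labs) == 0) {
    return(tibble(label = integer(0), ar = numeric(0), area = numeric(0),
                  excluded = character(0)))
  }
  mom <- EBImage::computeFeatures.moment(label_mask)
  shp <- EBImage::computeFeatures.shape(label_mask)
  major <- mom[, "m.majoraxis"]
  minor <- major * sqrt(pmax(0, 1 - mom[, "m.eccentricity"]^2))
  border <- unique(c(label_mask[1, ], label_mask[nrow(label_mask), ],
                     label_mask[, 1], label_mask[, ncol(label_mask)]))
  tibble(
    label = labs,
    ar = unname(pmax(1, major / pmax(minor, .Machine$double.eps))),
    area = unname(shp[, "s.area"]) * pixel_size^2,
    excluded = ifelse(labs %in% border, "edge", "none"))
}

#' Percent of elongated cells
#'
#' The fraction (in percent) of non-excluded cells whose aspect ratio meets
#' the elongation threshold (AR >= 2 by convention; AR = 1 is a perfect
#' circle).
#'
#' @param shapes A data frame with an `ar` column and optionally an
#'   `excluded` column (`"none"` rows are kept).
#' @param threshold Elongation threshold on AR (default 2).
#' @return A single percentage in `[0, 100]`.
#' @examples
#' percent_elongated(tibble::tibble(ar = c(1, 1, 3, 2)))  # 50
#' @export
percent_elongated <- function(shapes, threshold = 2) {
  if (!is.data.frame(shapes) || !"ar" %in% names(shapes)) {
    abort("`shapes` must be a data frame with an `ar` column.",
          class = "mechanomir_schema_error")
  }
  if ("excluded" %in% names(shapes)) {
    shapes <- dplyr::filter(shapes, .data$excluded %in% "none" |
                                    is.na(.data$excluded))
  }
  if (nrow(shapes) == 0) {
    abort("No non-excluded cells to summarise.",
          class = "mechanomir_domain_error")
  }
  100 * mean(shapes$ar >= threshold)
}

#' Bin aspect ratios into a density histogram
#'
#' Fixed-width binning (default 0.1 AR) from AR = 1 up to an upper quantile
#' of the sample (99.5th by default, so a handful of extreme cells cannot
#' dictate the support). Densities are normalised by the full sample size,
#' so they integrate to the retained fraction of cells (~1).
#'
#' @param ar Numeric aspect ratios (> 1), or a data frame with an `ar`
#'   column (excluded rows dropped).
#' @param bin_width Bin width in AR units.
#' @param trim Upper quantile bounding the binned support.
#' @return An object of class `ar_histogram`: list with `bin_edges`,
#'   `mids`, `density`, `counts`, `n` (full sample size), `bin_width`.
#' @export
ar_histogram <- function(ar, bin_width = 0.1, trim = 0.995) {
  if (is.data.frame(ar)) {
    if ("excluded" %in% names(ar)) {
      ar <- dplyr::filter(ar, .data$excluded %in% "none" | is.na(.data$excluded))
    }
    ar <- ar$ar
  }
  ar <- ar[!is.na(ar)]
  if (length(ar) == 0 || any(ar < 1)) {
    abort("Aspect ratios must be >= 1 and non-empty.",
          class = "mechanomir_domain_error")
  }
  n <- length(ar)
  upper <- stats::quantile(ar, trim, names = FALSE)
  n_bins <- max(1L, ceiling((upper - 1) / bin_width))
  edges <- 1 + bin_width * (0:n_bins)
  idx <- findInterval(ar, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(bin_edges = edges, mids = edges[-1] - bin_width / 2,
         density = counts / (n * bin_width), counts = counts,
         n = n, bin_width = bin_width),
    class = "ar_histogram")
}

# mixture density model on x = AR - 1 given a flat parameter vector
# c(a1, mu1, s1[, a2, mu2, s2])
mixture_density <- function(x, pars) {
  k <- length(pars) / 3
  rowSums(vapply(seq_len(k), function(i) {
    shifted_lnorm_term(x, pars[3 * i - 2], pars[3 * i - 1], pars[3 * i])
  }, numeric(length(x))))
}

# bin-averaged mixture density over [lo, hi] on the x scale: what a density
# histogram estimates. Fitting this instead of the midpoint density removes
# the systematic bias that sharply peaked components suffer at finite bin
# width (a spurious lack of fit the extra 2-term parameters would absorb).
mixture_binned_density <- function(lo, hi, pars) {
  k <- length(pars) / 3
  rowSums(vapply(seq_len(k), function(i) {
    a <- pars[3 * i - 2]; mu <- pars[3 * i - 1]; s <- pars[3 * i]
    a * (stats::plnorm(hi, mu, s) - stats::plnorm(lo, mu, s)) / (hi - lo)
  }, numeric(length(lo))))
}

#' Peak location (mode) of a shifted-lognormal component
#'
#' For a component with log-location `mu` and log-dispersion `sigma` on
#' `x = AR - 1`, the density peaks at `AR = exp(mu - sigma^2) + 1`.
#'
#' @param mu Log-scale location.
#' @param sigma Log-scale dispersion (> 0).
#' @return The mode on the AR scale (vectorised).
#' @examples
#' component_mode(log(1.63) + 1e-4, 0.01)  # 2.63
#' @export
component_mode <- function(mu, sigma) {
  if (any(sigma <= 0)) {
    abort("`sigma` must be > 0.", class = "mechanomir_domain_error")
  }
  exp(mu - sigma^2) + 1
}

new_ar_mixture_fit <- function(components, sse, r2, hist, converged = TRUE) {
  structure(
    list(components = components, n_terms = nrow(components),
         sse = sse, r2 = r2, histogram = hist, converged = converged),
    class = "ar_mixture_fit")
}

#' Fit a 1- or 2-component shifted-lognormal mixture to an AR histogram
#'
#' Unweighted least-squares fit of the mixture density
#' `f(x) = sum_i a_i / (x sigma_i sqrt(2 pi)) exp(-(ln x - mu_i)^2 / (2 sigma_i^2))`
#' on `x = AR - 1` to the binned densities. The model is evaluated as the
#' bin-averaged density (component CDF increments over each bin divided by
#' the bin width) — the quantity a density histogram estimates — so sharply
#' peaked components are not penalised at finite bin width. Initial values
#' come from
#' method-of-moments on the binned sample (1 term) or a 2-means split of
#' `log(x)` (2 terms), followed by jittered multistarts; the best converged
#' start by SSE wins. Parameters are bounded (`a` in [0, 2], `sigma` in
#' [0.01, 2]) and components are returned ordered by ascending mode.
#'
#' @param hist An [ar_histogram()], or raw aspect ratios (binned with
#'   defaults first).
#' @param n_terms 1 or 2.
#' @param n_starts Number of jittered multistarts (default 5).
#' @return An object of class `ar_mixture_fit` with `components` (tibble:
#'   `term`, `a`, `mu`, `sigma`, `mode`), `n_terms`, `sse`, `r2`, and the
#'   histogram it was fit to. Use [tidy()] / [glance()] to extract these.
#' @seealso [select_model()], [fit_ar_mixture()]
#' @export
fit_ar_pdf <- function(hist, n_terms = 1, n_starts = 5) {
  if (!inherits(hist, "ar_histogram")) hist <- ar_histogram(hist)
  if (!n_terms %in% c(1, 2)) {
    abort("`n_terms` must be 1 or 2.", class = "mechanomir_domain_error")
  }
  if (length(hist$density) < 8 || hist$n < 50) {
    abort("Need >= 8 bins and >= 50 cells to fit.",
          class = "mechanomir_fit_error")
  }
  if (stats::var(hist$density) == 0) {
    abort("Zero-variance histogram: nothing to fit.",
          class = "mechanomir_fit_error")
  }
  x <- hist$mids - 1
  y <- hist$density
  # binned pseudo-sample for initialisation
  xs <- rep(x, hist$counts)
  logs <- log(xs)

  starts <- list()
  if (n_terms == 1) {
    s0 <- min(max(stats::sd(logs), 0.05), 1.5)
    starts[[1]] <- c(a1 = 1, mu1 = mean(logs), s1 = s0)
  } else {
    km <- withr::with_seed(1L, stats::kmeans(logs, centers = 2, nstart = 5))
    ord <- order(km$centers)
    grp <- match(km$cluster, ord)
    mu0 <- vapply(1:2, function(i) mean(logs[grp == i]), 0)
    s0 <- vapply(1:2, function(i) {
      s <- stats::sd(logs[grp == i]); if (is.na(s) || s < 0.02) 0.05 else min(s, 1.5)
    }, 0)
    w0 <- vapply(1:2, function(i) mean(grp == i), 0)
    starts[[1]] <- c(a1 = w0[1], mu1 = mu0[1], s1 = s0[1],
                     a2 = w0[2], mu2 = mu0[2], s2 = s0[2])
  }
  base <- starts[[1]]
  jit <- withr::with_seed(2L, purrr::map(seq_len(max(0, n_starts - 1)), function(i) {
    p <- base
    p[grepl("^mu", names(p))] <- p[grepl("^mu", names(p))] + stats::runif(n_terms, -0.25, 0.25)
    p[grepl("^s", names(p))] <- pmin(2, pmax(0.01, p[grepl("^s", names(p))] *
                                               exp(stats::runif(n_terms, -0.4, 0.4))))
    p[grepl("^a", names(p))] <- pmin(2, pmax(0.01, p[grepl("^a", names(p))] *
                                               exp(stats::runif(n_terms, -0.3, 0.3))))
    p
  }))
  starts <- c(starts, jit)

  lower <- rep(c(0, -5, 0.01), n_terms)
  upper <- rep(c(2, 3, 2), n_terms)
  fml <- if (n_terms == 1) {
    y ~ mixture_binned_density(lo, hi, c(a1, mu1, s1))
  } else {
    y ~ mixture_binned_density(lo, hi, c(a1, mu1, s1, a2, mu2, s2))
  }
  dat <- list(lo = hist$bin_edges[-length(hist$bin_edges)] - 1,
              hi = hist$bin_edges[-1] - 1, y = y)
  fits <- purrr::map(starts, function(st) {
    tryCatch(
      minpack.lm::nlsLM(fml, data = dat,
                        start = as.list(st), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    abort(sprintf("Mixture fit failed to converge from %d starts (n = %d, %d bins).",
                  length(starts), hist$n, length(hist$density)),
          class = "mechanomir_fit_error")
  }
  sses <- purrr::map_dbl(fits, ~ sum(stats::resid(.x)^2))
  best <- fits[[which.min(sses)]]
  pars <- stats::coef(best)
  comp <- tibble(
    term = seq_len(n_terms),
    a = unname(pars[seq(1, by = 3, length.out = n_terms)]),
    mu = unname(pars[seq(2, by = 3, length.out = n_terms)]),
    sigma = unname(pars[seq(3, by = 3, length.out = n_terms)])) %>%
    dplyr::mutate(mode = component_mode(.data$mu, .data$sigma)) %>%
    dplyr::arrange(.data$mode) %>%
    dplyr::mutate(term = dplyr::row_number())
  sse <- min(sses)
  r2 <- 1 - sse / sum((y - mean(y))^2)
  new_ar_mixture_fit(comp, sse, r2, hist)
}

#' Select between the 1- and 2-term mixture fits
#'
#' Goodness of fit is compared by SSE (with both fits on the same histogram,
#' the R-squared ranking is the same quantity restated). The 2-term model
#' carries three extra parameters which reduce the SSE even on pure noise,
#' so the reduction must clear a penalty tolerance: a nested-model F-test
#' on the binned residuals, with the 2-term fit kept only when its
#' improvement is significant at `f_alpha`. In addition, a second component
#' must describe a population, not a blip: if its scale weight is below
#' `min_weight` of the total (default 5% of cells) the 1-term fit is kept —
#' an unweighted least-squares fit can otherwise park an ultra-narrow
#' component on a single noisy bin. Ties and insufficient improvements go
#' to the 1-term fit. Should SSE and R-squared ever rank the fits
#' differently (possible only if the fits saw different histograms), SSE
#' governs and a warning is raised.
#'
#' @param fit1,fit2 The 1- and 2-term [fit_ar_pdf()] results on one
#'   histogram.
#' @param f_alpha Significance level of the extra-sum-of-squares F-test
#'   gating the 2-term model (default 0.001, deliberately conservative so
#'   a second population must be strongly supported).
#' @param min_weight Minimum fraction of the total scale weight the minor
#'   component must hold (default 0.05).
#' @return The selected `ar_mixture_fit`.
#' @export
select_model <- function(fit1, fit2, f_alpha = 0.001, min_weight = 0.05) {
  stopifnot(inherits(fit1, "ar_mixture_fit"), inherits(fit2, "ar_mixture_fit"))
  if (fit1$histogram$n != fit2$histogram$n ||
      length(fit1$histogram$density) != length(fit2$histogram$density)) {
    abort("Both fits must be on the same histogram.",
          class = "mechanomir_domain_error")
  }
  if (sign(fit1$sse - fit2$sse) != sign(fit2$r2 - fit1$r2) &&
      fit1$sse != fit2$sse && fit1$r2 != fit2$r2) {
    warn("SSE and R-squared rank the fits differently; using SSE.",
         class = "mechanomir_selection_warning")
  }
  one_term <- if (fit1$n_terms == 1) fit1 else fit2
  two_term <- if (fit1$n_terms == 2) fit1 else fit2
  n_bins <- length(one_term$histogram$density)
  df2 <- n_bins - 6
  if (df2 < 1 || two_term$sse <= 0) return(one_term)
  if (min(two_term$components$a) / sum(two_term$components$a) < min_weight) {
    return(one_term)
  }
  f_stat <- ((one_term$sse - two_term$sse) / 3) / (two_term$sse / df2)
  p <- stats::pf(f_stat, 3, df2, lower.tail = FALSE)
  if (!is.na(p) && p < f_alpha) two_term else one_term
}

#' Fit both mixture models and select one
#'
#' Convenience wrapper: bins the sample, fits the 1- and 2-term shifted
#' lognormal mixtures, and returns the SSE-selected model. Should the
#' 2-term fit fail to converge (e.g. on a narrow histogram with too few
#' informative bins to support 6 parameters), the 1-term fit is returned
#' with a warning.
#'
#' @inheritParams ar_histogram
#' @inheritParams select_model
#' @param ... Passed to [fit_ar_pdf()].
#' @return The selected `ar_mixture_fit`.
#' @examples
#' ar <- simulate_aspect_ratios("LN229-23Pa", n = 1000, seed = 7)
#' fit <- fit_ar_mixture(ar)
#' glance(fit)
#' @export
fit_ar_mixture <- function(ar, bin_width = 0.1, trim = 0.995,
                           f_alpha = 0.001, min_weight = 0.05, ...) {
  h <- ar_histogram(ar, bin_width = bin_width, trim = trim)
  fit1 <- fit_ar_pdf(h, 1, ...)
  fit2 <- tryCatch(fit_ar_pdf(h, 2, ...), mechanomir_fit_error = function(e) {
    warn("2-term fit did not converge; keeping the 1-term model.",
         class = "mechanomir_fit_warning")
    NULL
  })
  if (is.null(fit2)) return(fit1)
  select_model(fit1, fit2, f_alpha = f_alpha, min_weight = min_weight)
}

#' Is the secondary morphology population experimentally relevant?
#'
#' A fitted secondary population matters only if its peak sits at or beyond
#' the elongation threshold; a second mode below AR = 2 still describes
#' rounded cells.
#'
#' @param fit A selected `ar_mixture_fit`.
#' @param threshold Elongation threshold on AR (default 2).
#' @return `TRUE` iff the fit has two terms and the larger mode is at or
#'   above `threshold`.
#' @export
flag_relevant_secondary <- function(fit, threshold = 2) {
  stopifnot(inherits(fit, "ar_mixture_fit"))
  fit$n_terms == 2 && max(fit$components$mode) >= threshold
}

#' @export
print.ar_mixture_fit <- function(x, ...) {
  cat(sprintf("<ar_mixture_fit> %d-term, SSE = %.4g, R^2 = %.3f (n = %d)\n",
              x$n_terms, x$sse, x$r2, x$histogram$n))
  print(x$components)
  invisible(x)
}

#' @rdname fit_ar_pdf
#' @param x An `ar_mixture_fit`.
#' @export
tidy.ar_mixture_fit <- function(x, ...) x$components

#' @rdname fit_ar_pdf
#' @export
glance.ar_mixture_fit <- function(x, ...) {
  tibble(n_terms = x$n_terms, sse = x$sse, r2 = x$r2,
         n = x$histogram$n, n_bins = length(x$histogram$density),
         secondary_mode = if (x$n_terms == 2) max(x$components$mode) else NA_real_)
}

#' @rdname fit_ar_pdf
#' @param object An `ar_mixture_fit`.
#' @export
autoplot.ar_mixture_fit <- function(object, ...) {
  h <- object$histogram
  bars <- tibble(mid = h$mids, density = h$density)
  xx <- seq(min(h$bin_edges) + 1e-4, max(h$bin_edges), length.out = 400)
  pars <- as.vector(t(as.matrix(object$components[, c("a", "mu", "sigma")])))
  curve <- tibble(ar = xx, density = mixture_density(xx - 1, pars))
  ggplot(bars, aes(x = .data$mid, y = .data$density)) +
    geom_col(width = h$bin_width, fill = "grey80", colour = "grey50") +
    geom_line(data = curve, aes(x = .data$ar, y = .data$density),
              colour = "#b2182b", linewidth = 0.8) +
    labs(x = "Aspect ratio", y = "Density",
         title = sprintf("%d-term shifted-lognormal fit (R² = %.2f)",
                         object$n_terms, object$r2)) +
    theme_minimal()
}
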