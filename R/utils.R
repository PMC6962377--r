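# small shared helpers

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# density of one shifted-lognormal term on x = AR - 1 (unnormalised by `a`)
shifted_lnorm_term <- function(x, a, mu, sigma) {
  a * stats::dlnorm(x, meanlog = mu, sdlog = sigma)
}

# mixture CDF of AR for a preset-style mixture (weights/mus/sigmas)
mixture_cdf_ar <- function(ar, weights, mus, sigmas) {
  vapply(ar, function(t) {
    if (t <= 1) return(0)
    sum(weights * stats::plnorm(t - 1, meanlog = mus, sdlog = sigmas))
  }, numeric(1))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "mechanomir_domain_error")
  }
  invisible(x)
}
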