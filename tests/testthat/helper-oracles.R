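# Independent oracles used across the suite. Deliberately naive
# implementations: plain loops and closed forms, no shared code with R/.

# aspect ratio of one labeled object from raw second moments:
# sqrt of the eigenvalue ratio of the pixel-coordinate covariance.
moment_ar_oracle <- function(mask, label) {
  idx <- which(mask == label, arr.ind = TRUE)
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[1] / ev[2])
}

# brute-force interaction-node scoring by explicit set membership loops
score_node_oracle <- function(targets, de_ids, de_fc, enrichment_p,
                              alpha = 0.05) {
  targets <- unique(targets)
  n_de <- 0; cum <- 0
  for (t in targets) {
    if (t %in% de_ids) {
      n_de <- n_de + 1
      cum <- cum + abs(de_fc[[t]])
    }
  }
  list(intersects = enrichment_p < alpha,
       n_targets = length(targets), n_de_targets = n_de,
       percent_overlap = 100 * n_de / length(targets),
       cumulative_abs_fc = cum)
}

# CDF of a preset's shifted-lognormal mixture on the AR scale
preset_cdf <- function(preset_row, ar) {
  mix <- preset_row$mixture[[1]]
  vapply(ar, function(t) {
    if (t <= 1) return(0)
    sum(mix$weights * plnorm(t - 1, mix$mus, mix$sigmas))
  }, numeric(1))
}

# Kolmogorov-Smirnov distance between a sample and a callable CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

# minimal ar_mixture_fit stand-in for pure selection/flag logic tests
fake_fit <- function(modes, sse = 1, r2 = 0.9, n = 1000, n_bins = 30) {
  structure(
    list(components = tibble::tibble(
           term = seq_along(modes), a = 1 / length(modes),
           mu = log(modes - 1) + 0.01, sigma = 0.1, mode = modes),
         n_terms = length(modes), sse = sse, r2 = r2,
         histogram = list(n = n, density = rep(0.1, n_bins)),
         converged = TRUE),
    class = "ar_mixture_fit")
}

# a tiny labeled mask with a rectangle, a disk and a border-touching object
demo_mask <- function() {
  m <- matrix(0L, 80, 80)
  m[21:60, 11:20] <- 1L                      # 40 x 10 rectangle
  ctr <- c(55, 55); r <- 9
  for (i in seq_len(80)) for (j in seq_len(80)) {
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= r^2) m[i, j] <- 2L
  }
  m[1:6, 60:70] <- 3L                        # touches top border
  m
}
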