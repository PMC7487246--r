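# Independent brute-force oracles used to check the implementation.

# Threshold date by scanning every observed day and recomputing cumulative
# sums from the raw counts.
oracle_threshold <- function(doys, counts, q) {
  o <- order(doys)
  doys <- doys[o]
  counts <- counts[o]
  total <- sum(counts)
  for (i in seq_along(doys)) {
    if (sum(counts[seq_len(i)]) / total >= q - 1e-12) return(doys[i])
  }
  doys[length(doys)]
}

# Measure of the union of two intervals by day-by-day set computation on a
# fine grid.
oracle_union_measure <- function(int_a, int_b, step = 0.01) {
  lo <- min(int_a[1], int_b[1])
  hi <- max(int_a[2], int_b[2])
  if (hi == lo) return(0)
  x <- seq(lo, hi - step, by = step) + step / 2
  inside <- (x >= int_a[1] & x <= int_a[2]) | (x >= int_b[1] & x <= int_b[2])
  sum(inside) * step
}

# Two-sided exact binomial p-value by full enumeration of all 2^n outcomes.
oracle_binom_2n <- function(k, n, p0 = 0.5) {
  outcomes <- expand.grid(rep(list(0:1), n))
  ks <- rowSums(outcomes)
  probs <- p0^ks * (1 - p0)^(n - ks)
  pk <- dbinom(k, n, p0)
  sum(probs[dbinom(ks, n, p0) <= pk * (1 + 1e-9)])
}

# OLS coefficients from the normal equations.
oracle_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# AICc by direct arithmetic from RSS (p parameters = coefficients + sigma^2).
oracle_aicc <- function(rss, n, n_coef) {
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  p <- n_coef + 1
  -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# A tiny survey table built by hand: one site, both aspects, chosen species
# intervals expressed as uniform weekly counts.
make_surveys <- function(spec) {
  # spec: data.frame with site_id, aspect, plot_id, species_id, year,
  #       first_doy, last_doy (weekly counts of 10 across that range)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    doys <- seq(r$first_doy, r$last_doy, by = 7)
    tibble::tibble(site_id = r$site_id, aspect = r$aspect,
                   plot_id = r$plot_id, species_id = r$species_id,
                   year = r$year, doy = doys, count = 10)
  })
  dplyr::bind_rows(out)
}

# Noise-free generator settings: aspect offset and sensitivity are the only
# structure left, so south curves are exact time-shifted copies.
noise_free_config <- function(seed = 1, n_sites = 2, ...) {
  synthetic_config(seed = seed, n_sites = n_sites, turnover_fraction = 0,
                   var_site = 0, var_genotype = 0, var_plot_noise = 0,
                   temp_noise_sd_C = 0, site_temp_sd_C = 0,
                   poisson_noise = FALSE, plot_occupancy = 1,
                   years = c("2017" = 0), ...)
}
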