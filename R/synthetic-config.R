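#' Configuration for the synthetic paired-aspect landscape
#'
#' Builds the parameter set for [simulate_landscape()] and its component
#' generators. Defaults are calibrated to the grassland study conditions the
#' package emulates: 4 sites with paired north/south aspects less than 100 m
#' apart, 3 plots per aspect, weekly surveys March-June over four spring
#' seasons, a south-minus-north soil-temperature offset of 3.06 degC, and a
#' phenological sensitivity of 3.4 days earlier flowering per +1 degC.
#'
#' @param seed Integer seed governing all randomness downstream.
#' @param n_sites Number of sites, each with a paired N and S aspect.
#' @param plots_per_aspect Survey plots per aspect (one quadrat each).
#' @param season_window Integer vector `c(start_doy, end_doy)`; default
#'   `c(60, 181)` spans March-June.
#' @param survey_interval_days Days between surveys (weekly grid by default).
#' @param n_species_pool Size of the landscape species pool.
#' @param turnover_fraction Fraction of each site's species present on only
#'   one aspect (split between N-only and S-only).
#' @param aspect_temp_offset_C Soil-temperature offset, south minus north, degC.
#' @param sensitivity_days_per_C Days of flowering advance per +1 degC of
#'   March-May mean soil temperature.
#' @param curve_sd_days Spread (sd, days) of a species' unimodal flowering
#'   curve; 7 d gives a 5-95% species window of about 23 days.
#' @param abundance_mean Expected total inflorescences per species per plot
#'   over the season.
#' @param var_species_peak Variance (days^2) of species peak dates in the
#'   pool. The default 225 (sd 15 d) spreads community flowering so that the
#'   community 5-95% duration is roughly 3.29 * sqrt(225 + curve_sd^2) ~ 54 d.
#' @param var_site Variance (days^2) of site-level timing offsets.
#' @param var_genotype Variance (days^2) of plot-level genotype-composition
#'   timing offsets; forced to 0 in `fixed_genotype_mode`.
#' @param var_plot_noise Variance (days^2) of residual plot-by-year timing noise.
#' @param fixed_genotype_mode Emulate the common-genotype sown-subplot
#'   experiment: the genotype variance component is removed so that any
#'   aspect difference reflects plastic responses only.
#' @param years Named numeric vector: year labels with year-level temperature
#'   offsets (degC). Default spans 2015-2018 with 2017 the coolest year.
#' @param temp_noise_sd_C Gaussian noise sd (degC) per temperature reading.
#' @param site_temp_sd_C Between-site sd (degC) of baseline soil temperature.
#' @param diurnal_amplitude_C Amplitude of the diurnal temperature cycle.
#' @param hourly Generate hourly logger readings (as deployed loggers do);
#'   `FALSE` gives one reading per day.
#' @param poisson_noise Sample survey counts as Poisson around the expected
#'   curve; `FALSE` returns the expected counts themselves (a noise-free
#'   diagnostic mode).
#' @param site_richness_range Integer range from which each site's species
#'   richness is drawn uniformly.
#' @param plot_occupancy Probability that a species assigned to an aspect
#'   occupies a given plot in a given year (at least one species is always
#'   retained per plot).
#' @param peak_mean_doy Mean day-of-year of species peak flowering.
#' @param moisture_mean_vwc Baseline volumetric water content (percent).
#' @param moisture_aspect_log_ratio Log-scale moisture contrast delta with
#'   north = south * exp(delta); the default 0.085 gives roughly a 1.7% VWC
#'   north-minus-south difference at 20% VWC.
#' @param moisture_noise_sd Log-scale residual sd of moisture spot readings.
#' @param moisture_dates Named list (by year) of day-of-year vectors on which
#'   moisture is spot-measured.
#'
#' @return A list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' cfg$aspect_temp_offset_C
synthetic_config <- function(seed = 1L,
                             n_sites = 4L,
                             plots_per_aspect = 3L,
                             season_window = c(60L, 181L),
                             survey_interval_days = 7L,
                             n_species_pool = 32L,
                             turnover_fraction = 0.3,
                             aspect_temp_offset_C = 3.06,
                             sensitivity_days_per_C = 3.4,
                             curve_sd_days = 7,
                             abundance_mean = 50,
                             var_species_peak = 225,
                             var_site = 9,
                             var_genotype = 4,
                             var_plot_noise = 4,
                             fixed_genotype_mode = FALSE,
                             years = c("2015" = 0.5, "2016" = 0.2,
                                       "2017" = -0.9, "2018" = 0.3),
                             temp_noise_sd_C = 0.5,
                             site_temp_sd_C = 0.5,
                             diurnal_amplitude_C = 4,
                             hourly = TRUE,
                             poisson_noise = TRUE,
                             site_richness_range = c(10L, 22L),
                             plot_occupancy = 0.85,
                             peak_mean_doy = 120,
                             moisture_mean_vwc = 20,
                             moisture_aspect_log_ratio = 0.085,
                             moisture_noise_sd = 0.08,
                             moisture_dates = list(
                               "2016" = c(117, 147, 173),
                               "2017" = c(69, 157))) {
  cfg <- list(
    seed = as.integer(seed),
    n_sites = as.integer(n_sites),
    plots_per_aspect = as.integer(plots_per_aspect),
    season_window = as.integer(season_window),
    survey_interval_days = as.integer(survey_interval_days),
    n_species_pool = as.integer(n_species_pool),
    turnover_fraction = turnover_fraction,
    aspect_temp_offset_C = aspect_temp_offset_C,
    sensitivity_days_per_C = sensitivity_days_per_C,
    curve_sd_days = curve_sd_days,
    abundance_mean = abundance_mean,
    var_species_peak = var_species_peak,
    var_site = var_site,
    var_genotype = var_genotype,
    var_plot_noise = var_plot_noise,
    fixed_genotype_mode = isTRUE(fixed_genotype_mode),
    years = years,
    temp_noise_sd_C = temp_noise_sd_C,
    site_temp_sd_C = site_temp_sd_C,
    diurnal_amplitude_C = diurnal_amplitude_C,
    hourly = isTRUE(hourly),
    poisson_noise = isTRUE(poisson_noise),
    site_richness_range = as.integer(site_richness_range),
    plot_occupancy = plot_occupancy,
    peak_mean_doy = peak_mean_doy,
    moisture_mean_vwc = moisture_mean_vwc,
    moisture_aspect_log_ratio = moisture_aspect_log_ratio,
    moisture_noise_sd = moisture_noise_sd,
    moisture_dates = moisture_dates
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_sites >= 1L, cfg$plots_per_aspect >= 1L,
    length(cfg$season_window) == 2L,
    cfg$survey_interval_days >= 1L,
    cfg$n_species_pool >= 1L,
    cfg$abundance_mean > 0, cfg$curve_sd_days > 0,
    cfg$plot_occupancy > 0, cfg$plot_occupancy <= 1,
    length(cfg$years) >= 1L, !is.null(names(cfg$years))
  )
  if (cfg$season_window[2] <= cfg$season_window[1]) {
    stop("`season_window` must be an increasing [start_doy, end_doy] pair.",
         call. = FALSE)
  }
  if (cfg$turnover_fraction < 0 || cfg$turnover_fraction > 1) {
    stop("`turnover_fraction` must lie in [0, 1].", call. = FALSE)
  }
  vars <- c("var_species_peak", "var_site", "var_genotype", "var_plot_noise")
  bad <- vars[vapply(vars, function(v) cfg[[v]] < 0, logical(1))]
  if (length(bad)) {
    stop("Variance components must be non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$fixed_genotype_mode) cfg$var_genotype <- 0
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d sites x 2 aspects x %d plots; years: %s\n",
              x$n_sites, x$plots_per_aspect,
              paste(names(x$years), collapse = ", ")))
  cat(sprintf("  season DOY %d-%d, surveys every %d d, species pool %d\n",
              x$season_window[1], x$season_window[2],
              x$survey_interval_days, x$n_species_pool))
  cat(sprintf("  aspect offset %.2f degC; sensitivity %.1f d/degC; turnover %.2f\n",
              x$aspect_temp_offset_C, x$sensitivity_days_per_C,
              x$turnover_fraction))
  if (x$fixed_genotype_mode) cat("  fixed-genotype mode (genotype variance 0)\n")
  invisible(x)
}
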