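# March-May window (DOY) used for the flowering-season mean temperature
MARCH_MAY <- c(60L, 151L)

#' Simulate paired-aspect soil-temperature logger series
#'
#' Generates a soil-temperature series for every site x aspect x year: a
#' seasonal sinusoid plus a diurnal cycle (when `hourly`), a site baseline,
#' a year-level offset, the south-minus-north aspect offset, and Gaussian
#' reading noise. South readings exceed paired north readings by
#' `aspect_temp_offset_C` in expectation; with the noise sd at zero the
#' paired difference is exact.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `site_id`, `aspect`, `year`, `doy`, `hour`,
#'   `soil_temp_C`, ordered deterministically; identical for identical seeds.
#' @export
simulate_temperature <- function(config) {
  cfg <- validate_synthetic_config(config)
  sw <- cfg$season_window
  doys <- seq(sw[1], sw[2])
  hours <- if (cfg$hourly) 0:23 else 12L
  site_ids <- sprintf("site%d", seq_len(cfg$n_sites))
  yrs <- as.integer(names(cfg$years))

  withr::with_seed(cfg$seed, {
    site_base <- stats::setNames(
      rnorm(cfg$n_sites, 0, cfg$site_temp_sd_C), site_ids)
    grid <- tidyr::expand_grid(
      site_id = site_ids, aspect = c("N", "S"), year = yrs,
      doy = doys, hour = as.integer(hours))
    grid <- dplyr::arrange(grid, .data$site_id, .data$aspect, .data$year,
                           .data$doy, .data$hour)
    seasonal <- 13 + 7 * sin(2 * pi * (grid$doy - 110) / 365)
    diurnal <- if (cfg$hourly) {
      cfg$diurnal_amplitude_C * sin(2 * pi * (grid$hour - 9) / 24)
    } else 0
    aspect_term <- ifelse(grid$aspect == "S", 1, -1) *
      cfg$aspect_temp_offset_C / 2
    year_term <- unname(cfg$years[as.character(grid$year)])
    noise <- if (cfg$temp_noise_sd_C > 0) {
      rnorm(nrow(grid), 0, cfg$temp_noise_sd_C)
    } else 0
    grid$soil_temp_C <- seasonal + diurnal + site_base[grid$site_id] +
      aspect_term + year_term + noise
    grid
  })
}

#' Simulate weekly inflorescence surveys
#'
#' Draws a species pool with Gaussian-spread peak flowering dates, assigns
#' species to sites and aspects (a `turnover_fraction` of each site's species
#' occur on one aspect only), and realises each species x plot x year peak as
#'
#' pool peak + site effect + genotype effect + plot noise
#'   - sensitivity * (plot March-May mean temperature - landscape mean).
#'
#' Expected counts follow a discretised Gaussian curve (sd `curve_sd_days`)
#' normalised over the weekly survey grid to total `abundance_mean`, and are
#' sampled with Poisson noise unless `poisson_noise = FALSE`. Zero-count
#' survey records are retained so that downstream curves have full support.
#'
#' @param config A [synthetic_config()].
#' @param temperature Output of [simulate_temperature()] (must cover the
#'   season for every site x aspect x year).
#' @return A tibble of survey records: `site_id`, `aspect`, `plot_id`,
#'   `species_id`, `year`, `doy`, `count`.
#' @export
simulate_surveys <- function(config, temperature) {
  cfg <- validate_synthetic_config(config)
  sw <- cfg$season_window
  survey_doys <- seq(sw[1], sw[2], by = cfg$survey_interval_days)
  site_ids <- sprintf("site%d", seq_len(cfg$n_sites))
  yrs <- as.integer(names(cfg$years))

  daily <- daily_mean_temperature(temperature)
  tmeans <- daily |>
    dplyr::filter(.data$doy >= MARCH_MAY[1], .data$doy <= MARCH_MAY[2]) |>
    dplyr::summarise(mean_temp = mean(.data$daily_mean_C),
                     .by = c("site_id", "aspect", "year"))
  need <- tidyr::expand_grid(site_id = site_ids, aspect = c("N", "S"),
                             year = yrs)
  miss <- dplyr::anti_join(need, tmeans,
                           by = c("site_id", "aspect", "year"))
  if (nrow(miss) > 0) {
    stop("Temperature series does not cover the season for every plot's ",
         "aspect (missing ", nrow(miss), " site/aspect/year combinations).",
         call. = FALSE)
  }
  t_landscape <- mean(tmeans$mean_temp)

  withr::with_seed(cfg$seed + 1L, {
    pool <- tibble::tibble(
      species_id = sprintf("sp%02d", seq_len(cfg$n_species_pool)),
      pool_peak = rnorm(cfg$n_species_pool, cfg$peak_mean_doy,
                        sqrt(cfg$var_species_peak)))
    site_eff <- stats::setNames(
      rnorm(cfg$n_sites, 0, sqrt(cfg$var_site)), site_ids)

    # species -> site x aspect assignment implementing turnover_fraction,
    # redrawn each year: annual grassland communities reassemble yearly,
    # and both presence and turnover are defined per site-year downstream
    rr <- pmin(cfg$site_richness_range, cfg$n_species_pool)
    presence <- dplyr::bind_rows(lapply(yrs, function(y) {
      dplyr::bind_rows(lapply(site_ids, function(s) {
        richness <- if (rr[1] == rr[2]) rr[1] else sample(rr[1]:rr[2], 1L)
        spp <- sample(pool$species_id, richness)
        n_turn <- round(cfg$turnover_fraction * richness)
        n_uni_n <- ceiling(n_turn / 2)
        n_uni_s <- n_turn - n_uni_n
        side <- rep("both", richness)
        if (n_uni_n > 0) side[seq_len(n_uni_n)] <- "N"
        if (n_uni_s > 0) side[n_uni_n + seq_len(n_uni_s)] <- "S"
        tibble::tibble(year = y, site_id = s, species_id = spp,
                       side = side)
      }))
    }))
    presence <- dplyr::bind_rows(
      presence |> dplyr::filter(.data$side != "S") |>
        dplyr::mutate(aspect = "N"),
      presence |> dplyr::filter(.data$side != "N") |>
        dplyr::mutate(aspect = "S")) |>
      dplyr::select("year", "site_id", "aspect", "species_id")

    plot_ids <- sprintf("p%d", seq_len(cfg$plots_per_aspect))
    grid <- tidyr::expand_grid(presence, plot_id = plot_ids) |>
      dplyr::arrange(.data$year, .data$site_id, .data$aspect, .data$plot_id,
                     .data$species_id)
    grid$geno_eff <- if (cfg$var_genotype > 0) {
      rnorm(nrow(grid), 0, sqrt(cfg$var_genotype))
    } else 0
    grid$plot_noise <- if (cfg$var_plot_noise > 0) {
      rnorm(nrow(grid), 0, sqrt(cfg$var_plot_noise))
    } else 0
    grid$occupied <- stats::runif(nrow(grid)) <= cfg$plot_occupancy
    # every plot keeps at least one species per year
    grid <- grid |>
      dplyr::mutate(occupied = if (any(.data$occupied)) .data$occupied else
                      dplyr::row_number() == 1L,
                    .by = c("year", "site_id", "aspect", "plot_id"))
    grid <- dplyr::filter(grid, .data$occupied)

    grid <- grid |>
      dplyr::left_join(pool, by = "species_id") |>
      dplyr::left_join(tmeans, by = c("site_id", "aspect", "year"))
    grid$peak <- grid$pool_peak + site_eff[grid$site_id] + grid$geno_eff +
      grid$plot_noise -
      cfg$sensitivity_days_per_C * (grid$mean_temp - t_landscape)

    mass_in <- pnorm(sw[2], grid$peak, cfg$curve_sd_days) -
      pnorm(sw[1], grid$peak, cfg$curve_sd_days)
    if (any(mass_in < 1e-8)) {
      off <- grid[mass_in < 1e-8, ]
      stop("Flowering-curve mass falls entirely outside the season window ",
           "for: ",
           paste(unique(paste0(off$site_id, "/", off$species_id, " (peak ",
                               round(off$peak, 1), ")")), collapse = ", "),
           call. = FALSE)
    }

    w <- outer(grid$peak, survey_doys,
               function(p, d) dnorm(d, p, cfg$curve_sd_days))
    lambda <- cfg$abundance_mean * w / rowSums(w)

    # expand_grid keeps grid-row order with doy varying fastest, matching
    # the row-major unrolling of lambda below
    out <- tidyr::expand_grid(
      dplyr::select(grid, "site_id", "aspect", "plot_id", "species_id",
                    "year"),
      doy = as.integer(survey_doys))
    lam <- as.vector(t(lambda))
    out$count <- if (cfg$poisson_noise) {
      as.numeric(rpois(length(lam), lam))
    } else {
      lam
    }
    dplyr::select(out, "site_id", "aspect", "plot_id", "species_id", "year",
                  "doy", "count")
  })
}

#' Simulate soil-moisture spot measurements
#'
#' Volumetric water content is log-normal: north aspects are moister than
#' south by a factor `exp(moisture_aspect_log_ratio)`, with site offsets, a
#' mild seasonal drydown, and log-scale reading noise.
#'
#' @param config A [synthetic_config()].
#' @return A tibble: `site_id`, `aspect`, `year`, `doy`, `vwc_pct`.
#' @export
simulate_moisture <- function(config) {
  cfg <- validate_synthetic_config(config)
  site_ids <- sprintf("site%d", seq_len(cfg$n_sites))
  yrs <- intersect(names(cfg$moisture_dates), names(cfg$years))
  dates <- dplyr::bind_rows(lapply(yrs, function(y) {
    tibble::tibble(year = as.integer(y),
                   doy = as.integer(cfg$moisture_dates[[y]]))
  }))
  withr::with_seed(cfg$seed + 2L, {
    site_eff <- stats::setNames(rnorm(cfg$n_sites, 0, 0.1), site_ids)
    grid <- tidyr::expand_grid(site_id = site_ids, aspect = c("N", "S"),
                               dates) |>
      dplyr::arrange(.data$site_id, .data$aspect, .data$year, .data$doy)
    log_vwc <- log(cfg$moisture_mean_vwc) + site_eff[grid$site_id] +
      ifelse(grid$aspect == "N", 1, -1) * cfg$moisture_aspect_log_ratio / 2 -
      0.004 * (grid$doy - 120) +
      rnorm(nrow(grid), 0, cfg$moisture_noise_sd)
    grid$vwc_pct <- exp(log_vwc)
    grid
  })
}

#' Simulate a full synthetic landscape
#'
#' Runs [simulate_temperature()], [simulate_surveys()] and
#' [simulate_moisture()] under one seed and collects the generating
#' parameters in a `truth` table for parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `surveys`, `temperature`, `moisture`,
#'   `truth` (tibbles) and `config`.
#' @export
#' @examples
#' land <- simulate_landscape(synthetic_config(seed = 42, n_sites = 2,
#'                                             years = c("2017" = 0)))
#' head(land$surveys)
simulate_landscape <- function(config) {
  cfg <- validate_synthetic_config(config)
  temperature <- simulate_temperature(cfg)
  surveys <- simulate_surveys(cfg, temperature)
  moisture <- simulate_moisture(cfg)
  truth <- tibble::tibble(
    param = c("seed", "n_sites", "plots_per_aspect", "aspect_temp_offset_C",
              "sensitivity_days_per_C", "turnover_fraction", "curve_sd_days",
              "abundance_mean", "var_species_peak", "var_site",
              "var_genotype", "var_plot_noise", "fixed_genotype_mode"),
    value = as.numeric(c(cfg$seed, cfg$n_sites, cfg$plots_per_aspect,
                         cfg$aspect_temp_offset_C,
                         cfg$sensitivity_days_per_C, cfg$turnover_fraction,
                         cfg$curve_sd_days, cfg$abundance_mean,
                         cfg$var_species_peak, cfg$var_site,
                         cfg$var_genotype, cfg$var_plot_noise,
                         cfg$fixed_genotype_mode)))
  list(surveys = surveys, temperature = temperature, moisture = moisture,
       truth = truth, config = cfg)
}

#' Write a simulated (or field) dataset to tidy CSV files
#'
#' Writes `surveys.csv`, `temperature.csv`, `moisture.csv` and `truth.csv`
#' into `dir`. Refuses to overwrite existing files unless `overwrite = TRUE`.
#'
#' @param data A list with any of `surveys`, `temperature`, `moisture`,
#'   `truth` (e.g. from [simulate_landscape()]).
#' @param dir Output directory (created if needed).
#' @param overwrite Allow replacing existing files.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, overwrite = FALSE) {
  stopifnot(is.list(data))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- intersect(c("surveys", "temperature", "moisture", "truth"),
                     names(data))
  paths <- file.path(dir, paste0(parts, ".csv"))
  clash <- paths[file.exists(paths)]
  if (length(clash) > 0 && !overwrite) {
    stop("Refusing to overwrite existing file(s): ",
         paste(basename(clash), collapse = ", "),
         ". Use overwrite = TRUE.", call. = FALSE)
  }
  for (i in seq_along(parts)) {
    readr::write_csv(data[[parts[i]]], paths[i])
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the CSV files.
#' @return A list with the tibbles found in `dir` (same types as written,
#'   so write/read round-trips are lossless).
#' @export
read_dataset <- function(dir) {
  specs <- list(
    surveys = readr::cols(site_id = "c", aspect = "c", plot_id = "c",
                          species_id = "c", year = "i", doy = "i",
                          count = "d"),
    temperature = readr::cols(site_id = "c", aspect = "c", year = "i",
                              doy = "i", hour = "i", soil_temp_C = "d"),
    moisture = readr::cols(site_id = "c", aspect = "c", year = "i",
                           doy = "i", vwc_pct = "d"),
    truth = readr::cols(param = "c", value = "d"))
  out <- list()
  for (part in names(specs)) {
    path <- file.path(dir, paste0(part, ".csv"))
    if (file.exists(path)) {
      out[[part]] <- readr::read_csv(path, col_types = specs[[part]],
                                     progress = FALSE)
    }
  }
  out
}
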