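#' Daily mean soil temperature per sensor
#'
#' @param temperature Logger records (`site_id`, `aspect`, `year`, `doy`,
#'   `soil_temp_C`; an `hour` column, if present, is averaged over).
#' @return A tibble: `site_id`, `aspect`, `year`, `doy`, `daily_mean_C`.
#' @export
daily_mean_temperature <- function(temperature) {
  temperature |>
    dplyr::summarise(daily_mean_C = mean(.data$soil_temp_C),
                     .by = c("site_id", "aspect", "year", "doy")) |>
    dplyr::arrange(.data$site_id, .data$aspect, .data$year, .data$doy)
}

#' Growing degree-day accumulation
#'
#' Daily contribution `max(0, daily mean - base_C)` accumulated over the
#' window (base 5 degC by default). Uses daily means rather than hourly
#' integration; pass pre-aggregated daily data or hourly records alike.
#'
#' @param temperature Logger records as in [daily_mean_temperature()].
#' @param base_C Base temperature, degC.
#' @param window `c(start_doy, end_doy)` accumulation window (March-June
#'   by default).
#' @return A tibble per sensor-year with `doy`, `gdd_daily` and
#'   `cum_gdd` (non-decreasing, starting from the first window day).
#' @export
#' @examples
#' temp <- data.frame(site_id = "a", aspect = "N", year = 2017,
#'                    doy = 60:69, soil_temp_C = 15)
#' max(growing_degree_days(temp, window = c(60, 69))$cum_gdd)  # 100
growing_degree_days <- function(temperature, base_C = 5,
                                window = c(60L, 181L)) {
  daily <- daily_mean_temperature(temperature) |>
    dplyr::filter(.data$doy >= window[1], .data$doy <= window[2])
  if (nrow(daily) == 0) {
    stop("No temperature data inside the accumulation window.",
         call. = FALSE)
  }
  gaps <- daily |>
    dplyr::summarise(max_gap = max(diff(c(window[1] - 1L, .data$doy))),
                     .by = c("site_id", "aspect", "year"))
  if (any(gaps$max_gap > 7)) {
    bad <- gaps[gaps$max_gap > 7, ]
    stop("Temperature gap(s) longer than 7 days in: ",
         paste(paste0(bad$site_id, "/", bad$aspect, "/", bad$year),
               collapse = ", "),
         ". Fill them first with gap_fill_temperature().", call. = FALSE)
  }
  daily |>
    dplyr::mutate(gdd_daily = pmax(0, .data$daily_mean_C - base_C)) |>
    dplyr::mutate(cum_gdd = cumsum(.data$gdd_daily),
                  .by = c("site_id", "aspect", "year")) |>
    dplyr::select("site_id", "aspect", "year", "doy", "gdd_daily",
                  "cum_gdd")
}

#' Sign test of paired south vs north degree-day totals
#'
#' Counts the site-years in which the south aspect accumulated more
#' degree-days than its paired north aspect and tests the count against a
#' fair coin with the exact two-sided binomial test. Exact ties are
#' excluded.
#'
#' @param gdd Output of [growing_degree_days()] (season totals are taken
#'   as each sensor-year's final `cum_gdd`).
#' @return A list: `k` (south higher), `n` (non-tied pairs), `n_ties`,
#'   `p_value`.
#' @export
gdd_sign_test <- function(gdd) {
  totals <- gdd |>
    dplyr::summarise(total = .data$cum_gdd[which.max(.data$doy)],
                     .by = c("site_id", "aspect", "year")) |>
    tidyr::pivot_wider(names_from = "aspect", values_from = "total") |>
    dplyr::filter(!is.na(.data$N), !is.na(.data$S))
  tie <- totals$S == totals$N
  k <- sum(totals$S > totals$N)
  n <- sum(!tie)
  list(k = k, n = n, n_ties = sum(tie),
       p_value = if (n > 0) exact_binomial(k, n) else NA_real_)
}

#' Mean seasonal soil temperature per sensor
#'
#' Arithmetic mean of daily means within the window (March-May flowering
#' season by default), per site x aspect x year.
#'
#' @inheritParams growing_degree_days
#' @param window `c(start_doy, end_doy)`; default March-May.
#' @return A tibble with `mean_temp_C` per sensor-year.
#' @export
mean_seasonal_temperature <- function(temperature, window = c(60L, 151L)) {
  daily <- daily_mean_temperature(temperature) |>
    dplyr::filter(.data$doy >= window[1], .data$doy <= window[2])
  if (nrow(daily) == 0) {
    stop("No temperature data inside the requested window.", call. = FALSE)
  }
  daily |>
    dplyr::summarise(mean_temp_C = mean(.data$daily_mean_C),
                     .by = c("site_id", "aspect", "year"))
}

doy_month <- function(doy) {
  # month of a 1-based day-of-year, non-leap calendar
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(doy - 1, c(0, ends[-12]))
}

#' Fill gaps in a logger series from other years of the same sensor
#'
#' Each missing day is filled with the mean of the donor years' values on
#' that day, adjusted by the difference in air temperature between the
#' target year and the donor years over the gap day's month:
#' `filled = donor_mean(doy) + (air_target - air_donors)` with the air
#' means taken over the month containing the gap.
#'
#' @param target A tibble for one sensor-year: `doy`, `daily_mean_C`
#'   (missing days are absent rows or `NA` values), plus a `year` column
#'   or `target_year` argument.
#' @param donors Same-sensor daily series from other years: `year`, `doy`,
#'   `daily_mean_C`.
#' @param air Optional landscape air-temperature reference: `year`, `doy`,
#'   `air_temp_C`. Omitting it applies no adjustment.
#' @param window `c(start_doy, end_doy)` the series should cover.
#' @return The target series with every window day present, a
#'   `filled` logical column flagging imputed days.
#' @export
gap_fill_temperature <- function(target, donors, air = NULL,
                                 window = c(60L, 181L)) {
  stopifnot(all(c("doy", "daily_mean_C") %in% names(target)),
            all(c("year", "doy", "daily_mean_C") %in% names(donors)))
  target <- dplyr::filter(target, !is.na(.data$daily_mean_C))
  all_doys <- seq(window[1], window[2])
  missing_doys <- setdiff(all_doys, target$doy)
  observed <- target |>
    dplyr::filter(.data$doy >= window[1], .data$doy <= window[2]) |>
    dplyr::mutate(filled = FALSE)
  if (length(missing_doys) == 0) {
    return(dplyr::arrange(observed, .data$doy))
  }
  donor_means <- donors |>
    dplyr::filter(.data$doy %in% missing_doys) |>
    dplyr::summarise(donor_mean = mean(.data$daily_mean_C), .by = "doy")
  unfillable <- setdiff(missing_doys, donor_means$doy)
  if (length(unfillable) > 0) {
    stop("No donor-year data for DOY ",
         paste(utils::head(unfillable, 5), collapse = ", "),
         if (length(unfillable) > 5) " ..." else "",
         "; the gap cannot be filled.", call. = FALSE)
  }
  adj <- rep(0, nrow(donor_means))
  if (!is.null(air)) {
    target_year <- unique(target$year)
    donor_years <- unique(donors$year)
    months <- doy_month(donor_means$doy)
    for (m in unique(months)) {
      in_month <- doy_month(air$doy) == m
      a_t <- mean(air$air_temp_C[in_month & air$year %in% target_year])
      a_d <- mean(air$air_temp_C[in_month & air$year %in% donor_years])
      adj[months == m] <- a_t - a_d
    }
  }
  filled <- tibble::tibble(
    doy = donor_means$doy,
    daily_mean_C = donor_means$donor_mean + adj,
    filled = TRUE)
  if ("year" %in% names(observed) && nrow(observed) > 0) {
    filled$year <- observed$year[1]
  }
  dplyr::bind_rows(observed, filled) |>
    dplyr::arrange(.data$doy)
}

#' Aspect contrast in soil moisture
#'
#' Log-transforms volumetric water content (to meet residual normality)
#' and fits a fixed-effects model with aspect, site and measurement date
#' (categorical, which nests year) via [fit_linear()]. The aspect term is
#' tested by nested-model comparison against the model without aspect.
#'
#' @param moisture Records with `site_id`, `aspect`, `year`, `doy`,
#'   `vwc_pct` (> 0).
#' @return A list: `fit`, `F`, `p`, `log_contrast` (south minus north on
#'   the log scale), `vwc_contrast_pct` (north minus south, back-transformed
#'   at the geometric mean VWC).
#' @export
moisture_compare <- function(moisture) {
  if (any(moisture$vwc_pct <= 0)) {
    stop("Volumetric water content must be positive to log-transform.",
         call. = FALSE)
  }
  d <- moisture |>
    dplyr::mutate(log_vwc = log(.data$vwc_pct),
                  date = factor(paste(.data$year, .data$doy, sep = "-")))
  if (dplyr::n_distinct(d$aspect) < 2 || dplyr::n_distinct(d$date) < 2) {
    stop("Need at least two aspects and two measurement dates.",
         call. = FALSE)
  }
  full <- fit_linear(log_vwc ~ aspect + site_id + date, d)
  null <- fit_linear(log_vwc ~ site_id + date, d)
  cmp <- compare_nested(null, full)
  beta_s <- unname(coef(full$lm)["aspectS"])  # log(S) - log(N)
  gm <- exp(mean(d$log_vwc))
  list(fit = full, F = cmp$F, p = cmp$p,
       log_contrast = beta_s,
       vwc_contrast_pct = gm * (1 - exp(beta_s)))
}
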