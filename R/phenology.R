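#' Cumulative flowering-proportion curve
#'
#' Pools counts by survey date (summing across plots/species when the
#' records span more than one) and computes the cumulative proportion of the
#' season's total flower count reached by each date:
#' `cum_prop[i] = sum(counts through doy i) / total season count`.
#'
#' @param records A data frame with columns `doy` and `count` (extra columns
#'   are ignored; rows sharing a `doy` are summed).
#' @return A tibble with `doy` (strictly increasing), `count`, `cum_prop`,
#'   carrying attributes `total_count` and `no_flowering`. When the total
#'   count is zero the curve is flagged `no_flowering = TRUE` (`cum_prop` is
#'   `NA`) rather than raising an error; such entities are excluded
#'   downstream.
#' @export
#' @examples
#' cumulative_proportion(data.frame(doy = c(100, 107, 114),
#'                                  count = c(5, 10, 5)))
cumulative_proportion <- function(records) {
  stopifnot(all(c("doy", "count") %in% names(records)))
  if (nrow(records) == 0) {
    stop("Need at least one survey record to build a flowering curve.",
         call. = FALSE)
  }
  if (any(records$count < 0)) {
    stop("Counts must be non-negative.", call. = FALSE)
  }
  curve <- records |>
    dplyr::summarise(count = sum(.data$count), .by = "doy") |>
    dplyr::arrange(.data$doy) |>
    tibble::as_tibble()
  total <- sum(curve$count)
  if (total > 0) {
    curve$cum_prop <- cumsum(curve$count) / total
  } else {
    curve$cum_prop <- NA_real_
  }
  attr(curve, "total_count") <- total
  attr(curve, "no_flowering") <- total == 0
  curve
}

#' Threshold date of a flowering curve
#'
#' Returns the day-of-year at which the cumulative flowering proportion
#' reaches `q`. The default `"step"` convention returns the first observed
#' survey date whose cumulative proportion is at or above `q` (the date on
#' which the threshold "had been reached"); `"interp"` interpolates linearly
#' between the bracketing survey dates for sub-interval resolution, which
#' affects resolution but never the ordering of dates.
#'
#' @param curve A curve from [cumulative_proportion()].
#' @param q Proportion threshold in (0, 1]; 0.05, 0.5 and 0.95 give the
#'   start, midflowering and end dates.
#' @param method `"step"` (default) or `"interp"`.
#' @return A day-of-year (integer under `"step"`, numeric under `"interp"`).
#' @export
#' @examples
#' cv <- cumulative_proportion(data.frame(doy = c(100, 107, 114),
#'                                        count = c(5, 10, 5)))
#' threshold_date(cv, 0.5)
threshold_date <- function(curve, q, method = c("step", "interp")) {
  method <- match.arg(method)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1) {
    stop("`q` must be a single proportion in (0, 1].", call. = FALSE)
  }
  if (isTRUE(attr(curve, "no_flowering")) || all(is.na(curve$cum_prop))) {
    stop("Curve is flagged 'no flowering'; no threshold date exists.",
         call. = FALSE)
  }
  cp <- curve$cum_prop
  doy <- curve$doy
  i <- which(cp >= q - 1e-12)[1]
  if (is.na(i)) i <- length(cp)  # guards rounding at q = 1
  if (method == "step" || i == 1L) {
    return(doy[i])
  }
  # first qualifying date interpolated against the previous survey
  doy[i - 1] + (q - cp[i - 1]) / (cp[i] - cp[i - 1]) * (doy[i] - doy[i - 1])
}

#' Start, mid and end dates and flowering duration
#'
#' Summarises a flowering curve by its 5% (start), 50% (midflowering) and
#' 95% (end) cumulative-proportion dates, with
#' `duration_days = end - start`. When flowering was only observed on a
#' single survey date the duration is recorded as 1 day under
#' `single_date_rule` (flowering certainly spanned less than one survey
#' interval, but not zero days).
#'
#' @inheritParams threshold_date
#' @param single_date_rule Apply the 1-day duration rule when start = end.
#' @return A one-row tibble: `start_doy`, `mid_doy`, `end_doy`,
#'   `duration_days`, `total_count`.
#' @export
pheno_summary <- function(curve, single_date_rule = TRUE,
                          method = c("step", "interp")) {
  method <- match.arg(method)
  start <- threshold_date(curve, 0.05, method)
  mid <- threshold_date(curve, 0.50, method)
  end <- threshold_date(curve, 0.95, method)
  duration <- end - start
  if (duration == 0 && single_date_rule) duration <- 1
  tibble::tibble(start_doy = start, mid_doy = mid, end_doy = end,
                 duration_days = duration,
                 total_count = attr(curve, "total_count"))
}

level_keys <- function(level) {
  switch(level,
         plot = c("site_id", "aspect", "plot_id", "year"),
         aspect = c("site_id", "aspect", "year"),
         site = c("site_id", "year"),
         species_aspect = c("site_id", "aspect", "species_id", "year"),
         stop("Unknown aggregation level: ", level, call. = FALSE))
}

#' Phenology summaries for every entity at an aggregation level
#'
#' Groups survey records at the requested level (pooling counts over the
#' dimensions the level spans), builds each entity's cumulative curve, and
#' returns its threshold dates and duration. Entities with zero total count
#' are dropped (flagged, not an error).
#'
#' @param surveys Survey records (`site_id`, `aspect`, `plot_id`,
#'   `species_id`, `year`, `doy`, `count`).
#' @param level One of `"plot"` (counts pooled over a plot's species),
#'   `"aspect"` (pooled over plots and species), `"site"` (pooled over both
#'   aspects: the combined-slope curve), `"species_aspect"` (one species on
#'   one aspect, pooled over plots).
#' @inheritParams pheno_summary
#' @return A tibble keyed by the level's grouping columns with a `level`
#'   tag and the [pheno_summary()] columns.
#' @export
pheno_summaries <- function(surveys, level = "plot",
                            single_date_rule = TRUE,
                            method = c("step", "interp")) {
  method <- match.arg(method)
  keys <- level_keys(level)
  surveys |>
    dplyr::summarise(count = sum(.data$count),
                     .by = dplyr::all_of(c(keys, "doy"))) |>
    dplyr::filter(sum(.data$count) > 0, .by = dplyr::all_of(keys)) |>
    dplyr::reframe({
      cv <- cumulative_proportion(dplyr::pick("doy", "count"))
      pheno_summary(cv, single_date_rule, method)
    }, .by = dplyr::all_of(keys)) |>
    dplyr::mutate(level = level, .before = 1)
}
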