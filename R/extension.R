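#' Extension metrics from aspect and combined durations
#'
#' The headline resource-extension statistic. With `Longer` the longer of
#' the two single-aspect durations and `Combined` the duration with both
#' aspects present,
#'
#' `extension_days = Combined - Longer` and
#' `extension_pct = 100 * (Combined - Longer) / Longer`.
#'
#' The calculation is conservative by construction: it extends the longer
#' flowering slope rather than the shorter one.
#'
#' @param duration_south,duration_north,duration_combined Durations in days
#'   (vectorised).
#' @return A tibble with the inputs plus `longer`, `extension_days` and
#'   `extension_pct` (`NA` with a message where `longer` is 0).
#' @export
#' @examples
#' extension_metrics(16.2, 20.2, 25.6)  # 5.4 days extension
extension_metrics <- function(duration_south, duration_north,
                              duration_combined) {
  if (any(c(duration_south, duration_north, duration_combined) < 0,
          na.rm = TRUE)) {
    stop("Durations must be non-negative.", call. = FALSE)
  }
  longer <- pmax(duration_south, duration_north)
  ext_days <- duration_combined - longer
  if (any(longer == 0, na.rm = TRUE)) {
    message("`longer` is 0 for ", sum(longer == 0, na.rm = TRUE),
            " case(s); extension_pct reported as missing.")
  }
  tibble::tibble(
    duration_south = duration_south,
    duration_north = duration_north,
    duration_combined = duration_combined,
    longer = longer,
    extension_days = ext_days,
    extension_pct = ifelse(longer > 0, 100 * ext_days / longer, NA_real_))
}

#' Combined duration of two flowering intervals with gap removal
#'
#' Length of the union of a species' north- and south-aspect flowering
#' intervals. Any gap between the two intervals is removed from the
#' duration (a gap in time is not flowering time) and reported separately.
#'
#' @param interval_n,interval_s Numeric `c(start, end)` day-of-year pairs.
#' @return A list: `duration` (days of the union, gap excluded) and
#'   `gap_days` (`max(0, later start - earlier end)`).
#' @export
#' @examples
#' species_combined_duration(c(100, 105), c(110, 115))  # 10 d, gap 5 d
species_combined_duration <- function(interval_n, interval_s) {
  stopifnot(length(interval_n) == 2L, length(interval_s) == 2L)
  if (interval_n[1] > interval_n[2] || interval_s[1] > interval_s[2]) {
    stop("Intervals must satisfy start <= end.", call. = FALSE)
  }
  overlap <- max(0, min(interval_n[2], interval_s[2]) -
                   max(interval_n[1], interval_s[1]))
  gap <- max(0, max(interval_n[1], interval_s[1]) -
               min(interval_n[2], interval_s[2]))
  duration <- (interval_n[2] - interval_n[1]) +
    (interval_s[2] - interval_s[1]) - overlap
  list(duration = duration, gap_days = gap)
}

aspect_level_summaries <- function(surveys, aspect_agg, method,
                                   single_date_rule) {
  if (aspect_agg == "average") {
    pheno_summaries(surveys, "plot", single_date_rule, method) |>
      dplyr::summarise(start_doy = mean(.data$start_doy),
                       end_doy = mean(.data$end_doy),
                       duration_days = mean(.data$duration_days),
                       total_count = sum(.data$total_count),
                       .by = c("site_id", "aspect", "year"))
  } else {
    pheno_summaries(surveys, "aspect", single_date_rule, method)
  }
}

#' Community flowering-time extension per site and year
#'
#' For every site x year, computes the south, north and combined flowering
#' durations and the extension statistic. Aspect durations default to the
#' mean of the aspect's plot-level durations (`aspect_agg = "average"`,
#' matching per-plot threshold dates); `"pooled"` thresholds the aspect's
#' pooled counts instead. The combined duration defaults to re-thresholding
#' the counts pooled across both aspects (`combined = "pooled"`); the
#' interval-union value (union of the two aspect intervals, gaps removed)
#' is always computed alongside as `combined_union`.
#'
#' Pooling can yield a combined duration shorter than the longer aspect
#' under extreme abundance imbalance; such cases are reported with a
#' warning, never clamped. Site-years where only one aspect flowered carry
#' that aspect's duration with zero extension and `note = "single_aspect"`.
#'
#' @param surveys Survey records.
#' @param aspect_agg `"average"` (default) or `"pooled"`.
#' @param combined `"pooled"` (default) or `"union"`.
#' @param method Threshold convention, `"step"` or `"interp"`.
#' @param single_date_rule Apply the 1-day rule for single-date curves.
#' @return A tibble per site x year with durations, `combined_pooled`,
#'   `combined_union`, `gap_days`, `longer`, `extension_days`,
#'   `extension_pct` and `note`.
#' @export
community_extension <- function(surveys,
                                aspect_agg = c("average", "pooled"),
                                combined = c("pooled", "union"),
                                method = c("step", "interp"),
                                single_date_rule = TRUE) {
  aspect_agg <- match.arg(aspect_agg)
  combined <- match.arg(combined)
  method <- match.arg(method)

  asp <- aspect_level_summaries(surveys, aspect_agg, method,
                                single_date_rule)
  pooled <- pheno_summaries(surveys, "site", single_date_rule, method) |>
    dplyr::select("site_id", "year", combined_pooled = "duration_days")

  wide <- asp |>
    tidyr::pivot_wider(id_cols = c("site_id", "year"),
                       names_from = "aspect",
                       values_from = c("start_doy", "end_doy",
                                       "duration_days"))
  for (col in c("start_doy_N", "end_doy_N", "duration_days_N",
                "start_doy_S", "end_doy_S", "duration_days_S")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  uni <- mapply(function(sn, en, ss, es) {
    if (anyNA(c(sn, en, ss, es))) return(c(NA_real_, NA_real_))
    u <- species_combined_duration(c(sn, en), c(ss, es))
    c(u$duration, u$gap_days)
  }, wide$start_doy_N, wide$end_doy_N, wide$start_doy_S, wide$end_doy_S)
  wide$combined_union <- uni[1, ]
  wide$gap_days <- uni[2, ]

  out <- wide |>
    dplyr::left_join(pooled, by = c("site_id", "year")) |>
    dplyr::mutate(
      note = dplyr::case_when(
        is.na(.data$duration_days_N) | is.na(.data$duration_days_S) ~
          "single_aspect",
        TRUE ~ ""))

  single <- out$note == "single_aspect"
  ds <- out$duration_days_S
  dn <- out$duration_days_N
  dc <- if (combined == "pooled") out$combined_pooled else out$combined_union
  # one aspect absent: combined is the present aspect's duration, ext 0
  dc[single] <- pmax(ds[single], dn[single], na.rm = TRUE)
  ds[is.na(ds)] <- 0
  dn[is.na(dn)] <- 0

  res <- extension_metrics(ds, dn, dc)
  below <- !single & res$extension_days < 0 & combined == "pooled"
  if (any(below)) {
    warning(sum(below), " site-year(s) have pooled combined duration ",
            "shorter than the longer aspect (abundance imbalance); ",
            "values reported unclamped.", call. = FALSE)
  }
  tibble::tibble(
    site_id = out$site_id, year = out$year, level = "community",
    res,
    combined_pooled = out$combined_pooled,
    combined_union = out$combined_union,
    gap_days = out$gap_days,
    note = out$note)
}

#' Species-level flowering differences and extension
#'
#' For every species present (with flowering) on both aspects of a site in
#' a year: the north-minus-south start/mid/end date differences, each
#' aspect's duration, and the union-based combined duration with any gap
#' between the aspects removed.
#'
#' @inheritParams community_extension
#' @return A tibble per site x year x shared species with `diff_start`,
#'   `diff_mid`, `diff_end` (N - S), durations, `gap_days` and the
#'   extension columns.
#' @export
species_extension <- function(surveys, method = c("step", "interp"),
                              single_date_rule = TRUE) {
  method <- match.arg(method)
  sp <- pheno_summaries(surveys, "species_aspect", single_date_rule, method)
  wide <- sp |>
    tidyr::pivot_wider(id_cols = c("site_id", "species_id", "year"),
                       names_from = "aspect",
                       values_from = c("start_doy", "mid_doy", "end_doy",
                                       "duration_days")) |>
    dplyr::filter(!is.na(.data$duration_days_N),
                  !is.na(.data$duration_days_S))
  if (nrow(wide) == 0) {
    return(tibble::tibble())
  }
  uni <- mapply(function(sn, en, ss, es) {
    u <- species_combined_duration(c(sn, en), c(ss, es))
    c(u$duration, u$gap_days)
  }, wide$start_doy_N, wide$end_doy_N, wide$start_doy_S, wide$end_doy_S)
  combined <- uni[1, ]
  # raw interval lengths decide `longer` so that the union bound holds;
  # the 1-day rule is then applied to the reported values
  raw_n <- wide$end_doy_N - wide$start_doy_N
  raw_s <- wide$end_doy_S - wide$start_doy_S
  ext_days <- combined - pmax(raw_n, raw_s)
  if (single_date_rule) combined[combined == 0] <- 1
  res <- extension_metrics(wide$duration_days_S, wide$duration_days_N,
                           combined)
  res$extension_days <- ext_days
  res$extension_pct <- ifelse(res$longer > 0,
                              100 * ext_days / res$longer, NA_real_)
  tibble::tibble(
    site_id = wide$site_id, year = wide$year,
    species_id = wide$species_id, level = "species",
    diff_start = wide$start_doy_N - wide$start_doy_S,
    diff_mid = wide$mid_doy_N - wide$mid_doy_S,
    diff_end = wide$end_doy_N - wide$end_doy_S,
    res,
    gap_days = uni[2, ])
}

#' Sign test for aspect complementarity
#'
#' Tests whether the aspect that starts flowering earlier also ends earlier
#' more often than expected by chance (exact two-sided binomial at 0.5).
#' Site-years with a tie in either the start or the end date are excluded
#' from the test and counted separately (conservative).
#'
#' @param aspect_summaries Per site x aspect x year summaries with
#'   `start_doy` and `end_doy` (e.g. [pheno_summaries()] at `"aspect"`
#'   level, or the plot-averaged equivalent).
#' @return A list: `n_consistent`, `n_ties`, `n`, `p_value` (`NA` with a
#'   message if every pair is tied).
#' @export
complementarity_sign_test <- function(aspect_summaries) {
  wide <- aspect_summaries |>
    tidyr::pivot_wider(id_cols = c("site_id", "year"),
                       names_from = "aspect",
                       values_from = c("start_doy", "end_doy")) |>
    dplyr::filter(!is.na(.data$start_doy_N), !is.na(.data$start_doy_S))
  d_start <- wide$start_doy_N - wide$start_doy_S
  d_end <- wide$end_doy_N - wide$end_doy_S
  tie <- d_start == 0 | d_end == 0
  consistent <- sign(d_start) == sign(d_end) & !tie
  n <- sum(!tie)
  k <- sum(consistent)
  if (n == 0) {
    message("All site-year pairs are tied; no sign test performed.")
    return(list(n_consistent = 0L, n_ties = sum(tie), n = 0L,
                p_value = NA_real_))
  }
  list(n_consistent = k, n_ties = sum(tie), n = n,
       p_value = exact_binomial(k, n))
}

#' Species turnover between a site's aspects
#'
#' Absolute turnover per site x year: the number of species present (with
#' at least one flowering record) on only one of the two aspects,
#' `turnover = n_unique_north + n_unique_south`.
#'
#' @param surveys Survey records.
#' @return A tibble per site x year: `n_unique_north`, `n_unique_south`,
#'   `n_shared`, `turnover`, `richness_north`, `richness_south`.
#' @export
turnover_summary <- function(surveys) {
  pres <- surveys |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("site_id", "year", "aspect", "species_id")) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::summarise(on_n = any(.data$aspect == "N"),
                     on_s = any(.data$aspect == "S"),
                     .by = c("site_id", "year", "species_id"))
  pres |>
    dplyr::summarise(
      n_unique_north = sum(.data$on_n & !.data$on_s),
      n_unique_south = sum(.data$on_s & !.data$on_n),
      n_shared = sum(.data$on_n & .data$on_s),
      .by = c("site_id", "year")) |>
    dplyr::mutate(
      turnover = .data$n_unique_north + .data$n_unique_south,
      richness_north = .data$n_unique_north + .data$n_shared,
      richness_south = .data$n_unique_south + .data$n_shared)
}

#' Community extension with species turnover removed
#'
#' Restricts each site x year to the species present on both aspects and
#' recomputes the community extension. The difference between the full and
#' the shared-only extension is the turnover-attributed component (it may
#' be negative where within-species differences exceed between-species
#' ones). Site-years with no shared species yield a flagged missing row.
#'
#' @inheritParams community_extension
#' @return As [community_extension()], with `level =
#'   "community_shared_only"`.
#' @export
extension_without_turnover <- function(surveys,
                                       aspect_agg = c("average", "pooled"),
                                       combined = c("pooled", "union"),
                                       method = c("step", "interp"),
                                       single_date_rule = TRUE) {
  shared <- surveys |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("site_id", "year", "aspect", "species_id")) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::summarise(n_aspects = dplyr::n_distinct(.data$aspect),
                     .by = c("site_id", "year", "species_id")) |>
    dplyr::filter(.data$n_aspects == 2L) |>
    dplyr::select("site_id", "year", "species_id")
  kept <- dplyr::semi_join(surveys, shared,
                           by = c("site_id", "year", "species_id"))
  all_sy <- dplyr::distinct(surveys, .data$site_id, .data$year)
  if (nrow(kept) == 0) {
    res <- tibble::tibble()
  } else {
    res <- community_extension(kept, aspect_agg, combined, method,
                               single_date_rule) |>
      dplyr::mutate(level = "community_shared_only")
  }
  missing <- dplyr::anti_join(all_sy, shared, by = c("site_id", "year"))
  if (nrow(missing) > 0) {
    missing <- dplyr::mutate(missing, level = "community_shared_only",
                             note = "no_shared_species")
    res <- dplyr::bind_rows(res, missing)
  }
  res
}

#' Regression of extension on absolute turnover
#'
#' Simple linear regression of community extension (days) on absolute
#' species turnover across site-years.
#'
#' @param data Data frame with columns `turnover` and `extension_days`.
#' @return A list: `slope`, `intercept`, `r_squared`, `p` (F test of the
#'   slope) and the underlying `fit`.
#' @export
turnover_extension_regression <- function(data) {
  d <- data[stats::complete.cases(data[c("turnover", "extension_days")]), ]
  if (nrow(d) < 3) {
    stop("Need at least 3 site-year points for the regression.",
         call. = FALSE)
  }
  if (var(d$turnover) == 0) {
    stop("Turnover is constant across points; slope is not identifiable.",
         call. = FALSE)
  }
  fit <- fit_linear(extension_days ~ turnover, d)
  null <- fit_linear(extension_days ~ 1, d)
  cmp <- compare_nested(null, fit)
  list(slope = unname(coef(fit$lm)["turnover"]),
       intercept = unname(coef(fit$lm)["(Intercept)"]),
       r_squared = fit$r_squared,
       p = cmp$p,
       fit = fit)
}

#' Yearly extension report table
#'
#' Averages per-site extension rows within year in the layout of the
#' study-style summary table: mean south, north and combined durations,
#' mean days extension with its range, and the mean extension percentage
#' (the mean of per-site percentages, which is why the printed yearly
#' percentage is generally not recomputable from the row means).
#'
#' @param results Output of [community_extension()],
#'   [extension_without_turnover()] or [species_extension()].
#' @return A tibble per year.
#' @export
extension_report <- function(results) {
  results |>
    dplyr::filter(!is.na(.data$extension_days)) |>
    dplyr::summarise(
      mean_south = mean(.data$duration_south),
      mean_north = mean(.data$duration_north),
      mean_combined = mean(.data$duration_combined),
      mean_days_extension = mean(.data$extension_days),
      min_days_extension = min(.data$extension_days),
      max_days_extension = max(.data$extension_days),
      mean_extension_pct = mean(.data$extension_pct, na.rm = TRUE),
      n_sites = dplyr::n(),
      .by = "year") |>
    dplyr::arrange(.data$year)
}
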