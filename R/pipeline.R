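#' Midflowering-vs-temperature regression stage
#'
#' Fits the fixed-effects model `midflowering ~ March-May mean temperature
#' + site + year` on plot-level community midflowering dates. Interpolated
#' threshold dates are used by default here because the step convention
#' quantises plot dates to the weekly survey grid, which only coarsens
#' resolution (the tabled phenology outputs keep the step convention).
#' The temperature slope is the phenological sensitivity in days per degC
#' (negative: warmer plots flower earlier).
#'
#' @param surveys Survey records.
#' @param temperature Logger records.
#' @param method Threshold convention for the mid dates.
#' @return A list: `fit` ([fit_linear()]), `slope` (days per degC),
#'   `r2_temp` (marginal R-squared of temperature) and the model `data`.
#' @export
midflowering_regression <- function(surveys, temperature,
                                    method = c("interp", "step")) {
  method <- match.arg(method)
  mids <- pheno_summaries(surveys, "plot", TRUE, method)
  temps <- mean_seasonal_temperature(temperature)
  d <- mids |>
    dplyr::left_join(temps, by = c("site_id", "aspect", "year")) |>
    dplyr::mutate(year = factor(.data$year))
  if (anyNA(d$mean_temp_C)) {
    stop("Temperature series does not cover every surveyed ",
         "site/aspect/year.", call. = FALSE)
  }
  rhs <- c("mean_temp_C",
           if (dplyr::n_distinct(d$site_id) > 1) "site_id",
           if (dplyr::n_distinct(d$year) > 1) "year")
  fit <- fit_linear(
    as.formula(paste("mid_doy ~", paste(rhs, collapse = " + "))), d)
  list(fit = fit,
       slope = unname(coef(fit$lm)["mean_temp_C"]),
       r2_temp = marginal_r2(fit, "mean_temp_C"),
       data = d)
}

#' Aspect model comparison for start, mid and end dates
#'
#' For each phenology date (start/mid/end, plot level) fits the null model
#' with year and site fixed effects and the full model adding aspect, and
#' reports df (parameters incl. residual variance), AICc, R-squared and
#' the nested F test of aspect.
#'
#' @param surveys Survey records.
#' @param method Threshold convention for plot dates.
#' @return A tibble with two rows (null/full) per response.
#' @export
aspect_model_comparison <- function(surveys, method = c("step", "interp")) {
  method <- match.arg(method)
  d <- pheno_summaries(surveys, "plot", TRUE, method) |>
    dplyr::mutate(year = factor(.data$year))
  base_rhs <- c(if (dplyr::n_distinct(d$year) > 1) "year",
                if (dplyr::n_distinct(d$site_id) > 1) "site_id")
  if (length(base_rhs) == 0) base_rhs <- "1"
  rows <- lapply(c(start = "start_doy", mid = "mid_doy", end = "end_doy"),
                 function(resp) resp)
  out <- dplyr::bind_rows(lapply(names(rows), function(nm) {
    resp <- rows[[nm]]
    null <- fit_linear(
      as.formula(paste(resp, "~", paste(base_rhs, collapse = " + "))), d)
    full <- fit_linear(
      as.formula(paste(resp, "~", paste(c(base_rhs, "aspect"),
                                        collapse = " + "))), d)
    cmp <- compare_nested(null, full)
    tibble::tibble(
      response = nm,
      model = c("year + site", "year + site + aspect"),
      df = c(null$k + 1, full$k + 1),
      AICc = c(aicc(null), aicc(full)),
      r_squared = c(null$r_squared, full$r_squared),
      F_ratio = c(cmp$F, NA_real_),
      p = c(cmp$p, NA_real_))
  }))
  out
}

fmt_row <- function(...) paste(sprintf("%-12s", c(...)), collapse = "")

format_extension_table <- function(tab) {
  lines <- fmt_row("Year", "Mean south", "Mean north", "Mean combined",
                   "Mean days extension", "Range of days extension",
                   "Mean extension")
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, fmt_row(
      tab$year[i],
      sprintf("%.1f", tab$mean_south[i]),
      sprintf("%.1f", tab$mean_north[i]),
      sprintf("%.1f", tab$mean_combined[i]),
      sprintf("%.2f", tab$mean_days_extension[i]),
      sprintf("%.1f-%.1f", tab$min_days_extension[i],
              tab$max_days_extension[i]),
      sprintf("%.1f%%", tab$mean_extension_pct[i])))
  }
  lines
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a landscape, writes the stage CSV files and a
#' plain-text report: phenology summaries, community/species/shared-only
#' extension with the turnover decomposition, microclimate summaries
#' (seasonal means, degree-day accumulation and its sign test, moisture
#' contrast), the aspect model comparison and the midflowering-temperature
#' regression. Identical config and seed give byte-identical output.
#'
#' @param config A [synthetic_config()] (its `seed` governs all
#'   randomness), or a list of tables as returned by [read_dataset()] /
#'   [simulate_landscape()] for pre-existing data.
#' @param out_dir Output directory.
#' @param overwrite Allow replacing existing outputs.
#' @param method Threshold convention for tabled phenology outputs.
#' @param aspect_agg,combined Community-extension conventions (see
#'   [community_extension()]).
#' @return Invisibly, a list with every stage's tables and fits.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE,
                         method = "step", aspect_agg = "average",
                         combined = "pooled") {
  if (inherits(config, "synthetic_config")) {
    land <- simulate_landscape(config)
    seed <- config$seed
  } else {
    stopifnot(is.list(config), "surveys" %in% names(config))
    land <- config
    seed <- NA_integer_
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_dataset(land, file.path(out_dir, "data"), overwrite = overwrite)

  surveys <- land$surveys
  temperature <- land$temperature

  summaries <- dplyr::bind_rows(
    pheno_summaries(surveys, "plot", method = method),
    pheno_summaries(surveys, "aspect", method = method),
    pheno_summaries(surveys, "site", method = method),
    pheno_summaries(surveys, "species_aspect", method = method))

  comm <- community_extension(surveys, aspect_agg, combined, method)
  shared <- extension_without_turnover(surveys, aspect_agg, combined,
                                       method)
  spp <- species_extension(surveys, method)
  turn <- turnover_summary(surveys)

  asp_sum <- aspect_level_summaries(surveys, aspect_agg, method, TRUE)
  sign_test <- complementarity_sign_test(asp_sum)

  turn_reg_data <- dplyr::left_join(comm, turn, by = c("site_id", "year"))
  turn_reg <- tryCatch(turnover_extension_regression(turn_reg_data),
                       error = function(e) NULL)

  seasonal <- mean_seasonal_temperature(temperature)
  contrast <- seasonal |>
    tidyr::pivot_wider(names_from = "aspect", values_from = "mean_temp_C") |>
    dplyr::mutate(contrast_C = .data$S - .data$N)
  gdd <- growing_degree_days(temperature)
  gdd_test <- gdd_sign_test(gdd)
  moist <- if (!is.null(land$moisture) && nrow(land$moisture) > 0) {
    moisture_compare(land$moisture)
  } else NULL

  models <- aspect_model_comparison(surveys, method)
  sens <- midflowering_regression(surveys, temperature)

  readr::write_csv(summaries, file.path(out_dir, "pheno_summaries.csv"))
  readr::write_csv(dplyr::bind_rows(comm, shared),
                   file.path(out_dir, "extension_results.csv"))
  readr::write_csv(spp, file.path(out_dir, "species_extension.csv"))
  readr::write_csv(turn, file.path(out_dir, "turnover.csv"))
  readr::write_csv(gdd, file.path(out_dir, "gdd.csv"))
  readr::write_csv(contrast, file.path(out_dir, "microclimate_report.csv"))
  readr::write_csv(models, file.path(out_dir, "model_comparison.csv"))

  lines <- c(
    "topophen pipeline report",
    "========================",
    sprintf("seed: %s", seed),
    sprintf("config hash: %s", rlang::hash(config)),
    sprintf("conventions: threshold=%s, aspect_agg=%s, combined=%s",
            method, aspect_agg, combined),
    "",
    "Microclimate",
    "------------",
    sprintf("Mean S-N March-May soil temperature contrast: %.2f degC",
            mean(contrast$contrast_C)),
    sprintf("GDD sign test (S > N): %d/%d, p = %.3g",
            gdd_test$k, gdd_test$n, gdd_test$p_value),
    if (!is.null(moist)) {
      sprintf("Moisture aspect contrast (N - S): %.2f%% VWC, p = %.3g",
              moist$vwc_contrast_pct, moist$p)
    },
    "",
    "Aspect model comparison (plot-level dates)",
    "------------------------------------------",
    fmt_row("response", "model", "df", "AICc", "R2", "F", "p"),
    vapply(seq_len(nrow(models)), function(i) fmt_row(
      models$response[i],
      models$model[i],
      models$df[i],
      sprintf("%.1f", models$AICc[i]),
      sprintf("%.3f", models$r_squared[i]),
      ifelse(is.na(models$F_ratio[i]), "",
             sprintf("%.1f", models$F_ratio[i])),
      ifelse(is.na(models$p[i]), "", sprintf("%.3g", models$p[i]))),
      character(1)),
    "",
    "Midflowering ~ temperature",
    "--------------------------",
    sprintf("slope = %.2f days/degC, marginal R2 of temperature = %.2f",
            sens$slope, sens$r2_temp),
    "",
    "Community extension (per-site means within year)",
    "------------------------------------------------",
    format_extension_table(extension_report(comm)),
    "",
    "Community extension without species turnover",
    "--------------------------------------------",
    format_extension_table(extension_report(shared)),
    "",
    if (nrow(spp) > 0) c(
      "Species-level extension (species on both aspects)",
      "-------------------------------------------------",
      format_extension_table(
        spp |> dplyr::summarise(
          mean_south = mean(.data$duration_south),
          mean_north = mean(.data$duration_north),
          mean_combined = mean(.data$duration_combined),
          mean_days_extension = mean(.data$extension_days),
          min_days_extension = min(.data$extension_days),
          max_days_extension = max(.data$extension_days),
          mean_extension_pct = mean(.data$extension_pct, na.rm = TRUE),
          .by = "year") |>
          dplyr::arrange(.data$year)),
      ""),
    "Complementarity",
    "---------------",
    sprintf("Earlier-starting aspect also ends earlier: %d/%d (%d ties), p = %.3g",
            sign_test$n_consistent, sign_test$n, sign_test$n_ties,
            sign_test$p_value),
    "",
    if (!is.null(turn_reg)) {
      sprintf("Extension ~ turnover: slope = %.2f d/species, R2 = %.2f, p = %.3g",
              turn_reg$slope, turn_reg$r_squared, turn_reg$p)
    })
  report_path <- file.path(out_dir, "report.txt")
  if (file.exists(report_path) && !overwrite) {
    stop("Refusing to overwrite ", report_path, "; use overwrite = TRUE.",
         call. = FALSE)
  }
  writeLines(unlist(lines), report_path)

  invisible(list(
    land = land, summaries = summaries, community = comm,
    shared_only = shared, species = spp, turnover = turn,
    sign_test = sign_test, turnover_regression = turn_reg,
    seasonal_temperature = seasonal, temperature_contrast = contrast,
    gdd = gdd, gdd_sign_test = gdd_test, moisture = moist,
    model_comparison = models, sensitivity = sens,
    report = file.path(out_dir, "report.txt")))
}

#' Diagnostic plot of cumulative flowering curves
#'
#' Plots the aspect-level cumulative flowering proportion per site and
#' year, the curve pair whose nonoverlap is the complementarity that
#' drives extension.
#'
#' @param surveys Survey records.
#' @return A ggplot object.
#' @export
plot_flowering_curves <- function(surveys) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("Package 'ggplot2' is required for plotting.", call. = FALSE)
  }
  curves <- surveys |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("site_id", "aspect", "year", "doy")) |>
    dplyr::arrange(.data$doy) |>
    dplyr::mutate(cum_prop = cumsum(.data$count) / sum(.data$count),
                  .by = c("site_id", "aspect", "year"))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$doy, y = .data$cum_prop,
                               colour = .data$aspect)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ggplot2::vars(.data$year),
                        ggplot2::vars(.data$site_id)) +
    ggplot2::labs(x = "Day of year", y = "Cumulative flowering proportion",
                  colour = "Aspect") +
    ggplot2::theme_minimal()
}
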