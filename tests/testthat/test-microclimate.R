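test_that("degree-days accumulate max(0, mean - base)", {
  temp <- data.frame(site_id = "a", aspect = "N", year = 2017L,
                     doy = 60:69, soil_temp_C = 15)
  g <- growing_degree_days(temp, base_C = 5, window = c(60, 69))
  expect_equal(max(g$cum_gdd), 100)
  expect_true(all(diff(g$cum_gdd) >= 0))

  cold <- transform(temp, soil_temp_C = c(5, 4, 3, 2, 5, 1, 0, -2, 5, 4))
  expect_equal(max(growing_degree_days(cold, window = c(60, 69))$cum_gdd), 0)
})

test_that("degree-days are monotone in temperature", {
  temp <- data.frame(site_id = "a", aspect = "N", year = 2017L,
                     doy = 60:89, soil_temp_C = seq(2, 16, length.out = 30))
  base <- growing_degree_days(temp, window = c(60, 89))
  bumped <- temp
  bumped$soil_temp_C[12] <- bumped$soil_temp_C[12] + 3
  up <- growing_degree_days(bumped, window = c(60, 89))
  expect_true(all(up$cum_gdd >= base$cum_gdd))
})

test_that("warmer south aspects accumulate strictly more degree-days", {
  cfg <- synthetic_config(seed = 2, n_sites = 3, temp_noise_sd_C = 0)
  gdd <- growing_degree_days(simulate_temperature(cfg))
  totals <- gdd |>
    dplyr::summarise(total = max(cum_gdd),
                     .by = c(site_id, aspect, year)) |>
    tidyr::pivot_wider(names_from = aspect, values_from = total)
  expect_true(all(totals$S > totals$N))
  st <- gdd_sign_test(gdd)
  expect_equal(st$k, st$n)
})

test_that("long logger gaps raise an error pointing to gap filling", {
  temp <- data.frame(site_id = "a", aspect = "N", year = 2017L,
                     doy = c(60:80, 95:181), soil_temp_C = 12)
  expect_error(growing_degree_days(temp), "gap_fill_temperature")
})

test_that("sign-test p-values match closed forms", {
  mk_gdd <- function(k, n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      s_total <- if (i <= k) 110 else 90
      tibble::tibble(site_id = paste0("s", i), aspect = c("N", "S"),
                     year = 2017L, doy = 181L, gdd_daily = 0,
                     cum_gdd = c(100, s_total))
    }))
  }
  expect_equal(gdd_sign_test(mk_gdd(17, 18))$p_value, 38 / 2^18,
               tolerance = 1e-10)
  expect_equal(gdd_sign_test(mk_gdd(9, 18))$p_value, 1.0)
  expect_equal(gdd_sign_test(mk_gdd(18, 18))$p_value, 2 * 0.5^18)
})

test_that("seasonal mean temperature averages daily means in the window", {
  temp <- data.frame(site_id = "a", aspect = "N", year = 2017L,
                     doy = 60:151, soil_temp_C = 12)
  expect_equal(mean_seasonal_temperature(temp)$mean_temp_C, 12)

  half <- temp
  half$soil_temp_C <- rep(c(10, 14), each = 46)
  expect_equal(mean_seasonal_temperature(half)$mean_temp_C, 12)

  expect_error(mean_seasonal_temperature(temp, window = c(200, 250)),
               "window")

  cfg <- synthetic_config(seed = 12, n_sites = 4)
  ms <- mean_seasonal_temperature(simulate_temperature(cfg))
  w <- tidyr::pivot_wider(ms, names_from = aspect,
                          values_from = mean_temp_C)
  expect_equal(mean(w$S - w$N), 3.06, tolerance = 0.05)
})

test_that("gap filling recovers truth when donors are informative", {
  truth <- tibble::tibble(year = 2017L, doy = 60:120,
                          daily_mean_C = 10 + 0.05 * (60:120))
  target <- truth[-c(10:15, 40), ]
  donor <- dplyr::mutate(truth, year = 2016L)

  # donor identical, no air adjustment: exact recovery
  filled <- gap_fill_temperature(target, donor, window = c(60, 120))
  expect_equal(filled$daily_mean_C, truth$daily_mean_C)
  expect_equal(sum(filled$filled), 7)

  # donor shifted +1 degC with an equal air-temperature difference: the
  # adjustment cancels the shift exactly
  donor_warm <- dplyr::mutate(donor, daily_mean_C = daily_mean_C + 1)
  air <- dplyr::bind_rows(
    tibble::tibble(year = 2016L, doy = 32:181, air_temp_C = 16),
    tibble::tibble(year = 2017L, doy = 32:181, air_temp_C = 15))
  filled2 <- gap_fill_temperature(target, donor_warm, air,
                                  window = c(60, 120))
  expect_equal(filled2$daily_mean_C, truth$daily_mean_C)

  # no donor coverage at the gap: unfillable
  expect_error(
    gap_fill_temperature(target, donor[donor$doy > 130, ],
                         window = c(60, 120)),
    "cannot be filled")
})

test_that("gap-fill error is bounded by the generator noise", {
  withr::with_seed(5, {
    base <- 10 + 0.05 * (60:181)
    sd_noise <- 0.5
    years <- lapply(2015:2017, function(y) {
      tibble::tibble(year = y, doy = 60:181,
                     daily_mean_C = base + rnorm(122, 0, sd_noise))
    })
    target_full <- years[[3]]
    drop <- sample(seq_len(122), 12)
    target <- target_full[-drop, ]
    donors <- dplyr::bind_rows(years[1:2])
    filled <- gap_fill_temperature(target, donors, window = c(60, 181))
    err <- filled$daily_mean_C[filled$filled] -
      target_full$daily_mean_C[sort(drop)]
    # filled = mean of 2 donors vs truth draw: sd = sd_noise * sqrt(1 + 1/2)
    expect_lt(sqrt(mean(err^2)), 3 * sd_noise * sqrt(1.5))
  })
})

test_that("moisture comparison recovers the log-scale aspect contrast", {
  south <- tidyr::expand_grid(site_id = c("a", "b", "c"),
                              year = c(2016L, 2017L),
                              doy = c(100L, 140L)) |>
    dplyr::mutate(aspect = "S",
                  vwc_pct = 18 + 2 * (site_id == "a") - 0.01 * doy)
  north <- dplyr::mutate(south, aspect = "N", vwc_pct = vwc_pct * exp(0.1))
  res <- moisture_compare(dplyr::bind_rows(south, north))
  expect_equal(res$log_contrast, -0.1, tolerance = 1e-8)
  expect_gt(res$vwc_contrast_pct, 0)  # north moister

  identical_aspects <- dplyr::bind_rows(
    south, dplyr::mutate(south, aspect = "N"))
  res0 <- moisture_compare(identical_aspects)
  expect_equal(res0$log_contrast, 0, tolerance = 1e-10)

  bad <- south
  bad$vwc_pct[1] <- 0
  expect_error(moisture_compare(dplyr::bind_rows(bad, north)), "positive")
})

test_that("synthetic moisture shows moister north aspects", {
  mo <- simulate_moisture(synthetic_config(seed = 3))
  res <- moisture_compare(mo)
  expect_lt(res$log_contrast, 0)
  # OLS contrast se = sd * sqrt(4/n) for a balanced two-level factor
  mc_se <- 0.08 * sqrt(4 / nrow(mo))
  expect_lt(abs(res$log_contrast - (-0.085)), 3 * mc_se)
})
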