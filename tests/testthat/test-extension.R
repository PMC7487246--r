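test_that("the extension formula behaves at its fixed points", {
  id <- extension_metrics(20, 20, 20)
  expect_equal(id$extension_days, 0)
  expect_equal(id$extension_pct, 0)

  r <- extension_metrics(10, 20, 25)
  expect_equal(r$longer, 20)
  expect_equal(r$extension_days, 5)
  expect_equal(r$extension_pct, 25)

  expect_error(extension_metrics(-1, 5, 5), "non-negative")
  expect_message(z <- extension_metrics(0, 0, 0), "missing")
  expect_true(is.na(z$extension_pct))
})

test_that("combined species duration removes gaps and unions overlap", {
  o <- species_combined_duration(c(100, 110), c(105, 118))
  expect_equal(o$duration, 18)
  expect_equal(o$gap_days, 0)

  g <- species_combined_duration(c(100, 105), c(110, 115))
  expect_equal(g$duration, 10)
  expect_equal(g$gap_days, 5)

  same <- species_combined_duration(c(100, 120), c(100, 120))
  expect_equal(same$duration, 20)
  expect_equal(same$gap_days, 0)

  expect_error(species_combined_duration(c(110, 100), c(100, 120)),
               "start <= end")
})

test_that("union duration matches the day-by-day oracle and its bounds", {
  withr::with_seed(13, {
    for (rep in 1:30) {
      a <- sort(sample(60:180, 2))
      b <- sort(sample(60:180, 2))
      u <- species_combined_duration(a, b)
      expect_equal(u$duration, oracle_union_measure(a, b),
                   tolerance = 0.05)
      len_a <- diff(a); len_b <- diff(b)
      expect_gte(u$duration + 1e-9, max(len_a, len_b))
      expect_lte(u$duration, len_a + len_b + 1e-9)
      # extension over the longer interval equals the nonoverlap of the
      # shorter one
      expect_gte(u$duration - max(len_a, len_b), -1e-9)
    }
  })
})

test_that("identical curves on both aspects give zero extension", {
  spec <- data.frame(
    site_id = "a", aspect = c("N", "N", "S", "S"),
    plot_id = c("p1", "p2", "p1", "p2"), species_id = "sp1",
    year = 2017L, first_doy = 100L, last_doy = 135L)
  comm <- community_extension(make_surveys(spec))
  expect_equal(comm$extension_days, 0)
  expect_equal(comm$extension_pct, 0)
  expect_equal(comm$duration_south, comm$duration_north)
})

test_that("a pure time shift yields combined ~ duration + shift under the
           union convention", {
  land <- simulate_landscape(noise_free_config(seed = 21, n_sites = 1))
  comm <- community_extension(land$surveys, aspect_agg = "pooled",
                              combined = "union", method = "interp")
  shift <- 3.4 * 3.06
  expect_equal(comm$duration_south, comm$duration_north, tolerance = 0.05)
  expect_equal(comm$extension_days, rep(shift, nrow(comm)), tolerance = 0.6)
})

test_that("a site-year with one flowering aspect is flagged with zero
           extension", {
  spec <- data.frame(site_id = "a", aspect = "N", plot_id = "p1",
                     species_id = "sp1", year = 2017L,
                     first_doy = 100L, last_doy = 121L)
  comm <- community_extension(make_surveys(spec))
  expect_equal(comm$note, "single_aspect")
  expect_equal(comm$extension_days, 0)
  expect_equal(comm$duration_combined, comm$duration_north)
})

test_that("complementarity sign test counts consistent pairs exactly", {
  mk <- function(n_consistent, n_total) {
    # consistent: N starts later and ends later; inconsistent: N starts
    # later but ends earlier
    tibble::tibble(
      site_id = paste0("s", seq_len(n_total)), year = 2017L) |>
      tidyr::expand_grid(aspect = c("N", "S")) |>
      dplyr::mutate(
        i = as.integer(sub("s", "", site_id)),
        start_doy = ifelse(aspect == "N", 105, 100),
        end_doy = dplyr::case_when(
          aspect == "S" ~ 130,
          i <= n_consistent ~ 135,
          TRUE ~ 125))
  }
  all16 <- complementarity_sign_test(mk(16, 16))
  expect_equal(all16$n_consistent, 16)
  expect_equal(all16$p_value, 2 * 0.5^16)

  half <- complementarity_sign_test(mk(8, 16))
  expect_equal(half$p_value, 1.0)
})

test_that("ties are excluded from the sign test and reported", {
  d <- tibble::tibble(
    site_id = rep(c("a", "b"), each = 2),
    year = 2017L,
    aspect = rep(c("N", "S"), 2),
    start_doy = c(100, 100, 105, 100),  # site a tied on start
    end_doy = c(120, 115, 125, 120))
  res <- complementarity_sign_test(d)
  expect_equal(res$n_ties, 1)
  expect_equal(res$n, 1)
  expect_equal(res$n_consistent, 1)
})

test_that("the noise-free landscape is consistent in every site-year", {
  land <- simulate_landscape(noise_free_config(seed = 2, n_sites = 3))
  asp <- pheno_summaries(land$surveys, "aspect", method = "interp")
  res <- complementarity_sign_test(asp)
  expect_equal(res$n_consistent, res$n)
  expect_gt(res$n, 0)
})

test_that("turnover counts species unique to one aspect", {
  spec <- data.frame(
    site_id = "a",
    aspect = c("N", "N", "N", "S", "S", "S", "S"),
    plot_id = "p1",
    species_id = c("A", "B", "C", "B", "C", "D", "E"),
    year = 2017L, first_doy = 100L, last_doy = 114L)
  t1 <- turnover_summary(make_surveys(spec))
  expect_equal(t1$n_unique_north, 1)
  expect_equal(t1$n_unique_south, 2)
  expect_equal(t1$n_shared, 2)
  expect_equal(t1$turnover, 3)
  expect_equal(t1$richness_north, 3)
  expect_equal(t1$richness_south, 4)

  ident <- spec[c(1:3, 1:3), ]
  ident$aspect <- rep(c("N", "S"), each = 3)
  expect_equal(turnover_summary(make_surveys(ident))$turnover, 0)

  disjoint <- data.frame(
    site_id = "a", aspect = c("N", "N", "S", "S", "S"), plot_id = "p1",
    species_id = c("A", "B", "C", "D", "E"), year = 2017L,
    first_doy = 100L, last_doy = 114L)
  expect_equal(turnover_summary(make_surveys(disjoint))$turnover, 5)
})

test_that("removing turnover reproduces the full result when turnover is 0", {
  land <- simulate_landscape(
    synthetic_config(seed = 6, n_sites = 2, turnover_fraction = 0,
                     plot_occupancy = 1, years = c("2017" = 0)))
  full <- community_extension(land$surveys)
  shared <- extension_without_turnover(land$surveys)
  expect_equal(shared$extension_days, full$extension_days)
  expect_equal(shared$duration_combined, full$duration_combined)
})

test_that("early/late unique species inflate full extension above
           shared-only", {
  # shared species identical across aspects; unique species strictly
  # earlier (S) and later (N)
  spec <- data.frame(
    site_id = "a",
    aspect = c("N", "S", "S", "N"),
    plot_id = "p1",
    species_id = c("shared", "shared", "early", "late"),
    year = 2017L,
    first_doy = c(100L, 100L, 65L, 135L),
    last_doy = c(128L, 128L, 86L, 156L))
  surveys <- make_surveys(spec)
  full <- community_extension(surveys)
  shared <- extension_without_turnover(surveys)
  expect_lte(shared$extension_days, full$extension_days)
})

test_that("full-community extension >= shared-only in most simulated
           site-years", {
  # pooled over 10 landscapes (160 site-years) so the direction is
  # resolved against Monte-Carlo noise
  ge <- unlist(lapply(1:10, function(s) {
    land <- simulate_landscape(synthetic_config(seed = 30 + s, n_sites = 4))
    suppressWarnings({
      full <- community_extension(land$surveys)
      shared <- extension_without_turnover(land$surveys)
    })
    j <- dplyr::inner_join(full, shared, by = c("site_id", "year"),
                           suffix = c("_full", "_shared"))
    j$extension_days_full >= j$extension_days_shared - 1e-9
  }))
  expect_gt(mean(ge), 0.5)
})

test_that("turnover-extension regression recovers structure", {
  colinear <- tibble::tibble(turnover = 1:5,
                             extension_days = 2 + 3 * (1:5))
  fit <- turnover_extension_regression(colinear)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 3)

  expect_error(turnover_extension_regression(
    tibble::tibble(turnover = rep(2, 5), extension_days = rnorm(5))),
    "constant")
  expect_error(turnover_extension_regression(
    tibble::tibble(turnover = 1:2, extension_days = 1:2)), "3 site-year")

  withr::with_seed(99, {
    x <- rep(0:8, 6)
    y <- 1 + 0.8 * x + rnorm(length(x), 0, 1)
    rec <- turnover_extension_regression(
      tibble::tibble(turnover = x, extension_days = y))
    se <- sqrt(1 / (var(x) * (length(x) - 1)))
    expect_lt(abs(rec$slope - 0.8), 4 * se)
  })
})

test_that("species-level extension respects the union bounds", {
  land <- simulate_landscape(synthetic_config(seed = 17, n_sites = 2))
  spp <- species_extension(land$surveys)
  expect_true(all(spp$extension_days >= -1e-9))
  expect_true(all(spp$gap_days >= 0))
  raw_longer <- pmax(spp$duration_north, spp$duration_south)
  expect_true(all(spp$duration_combined + 1e-9 >=
                    pmin(raw_longer, spp$duration_combined)))
})
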