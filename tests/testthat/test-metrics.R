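test_that("single-year climatology reproduces the year with SD 0", {
  s <- make_multiyear_series(2005, noise_sd = 0.1, seed = 2)
  expect_warning(cl <- build_climatology(s), "single year")
  expect_equal(nrow(cl), 365)
  expect_equal(cl$mean_dose, s$records$dose)
  expect_true(all(cl$sd_dose == 0))
  expect_true(all(cl$n_years == 1))
})

test_that("climatology matches a brute-force per-day recomputation on an 18-year record", {
  s <- make_multiyear_series(2004:2021, seed = 31)
  cl <- build_climatology(s)
  expect_equal(nrow(cl), 365)
  expect_true(all(cl$n_years == 18))
  rec <- s$records
  key <- format(rec$date, "%m-%d")
  rec <- rec[key != "02-29", ]
  key <- key[key != "02-29"]
  oracle_mean <- tapply(rec$dose, key, mean)
  oracle_sd <- tapply(rec$dose, key, stats::sd)
  got_key <- sprintf("%02d-%02d", cl$month, cl$day)
  expect_equal(cl$mean_dose, as.numeric(oracle_mean[got_key]))
  expect_equal(cl$sd_dose, as.numeric(oracle_sd[got_key]))
})

test_that("two years average to the midpoint and Feb 29 is dropped", {
  dates <- seq(as.Date("2004-01-01"), as.Date("2005-12-31"), by = "day")
  dose <- ifelse(format(dates, "%Y") == "2004", 1, 3)
  s <- duvb_series(geo_location("x", 50, 0),
                   tibble::tibble(date = dates, dose = dose, flag = "measured"))
  cl <- build_climatology(s)  # Feb 29 of 2004 is dropped, so no n = 1 days
  expect_equal(nrow(cl), 365)
  expect_false(any(cl$month == 2 & cl$day == 29))
  expect_equal(cl$mean_dose[!(cl$month == 2 & cl$day == 29)][1], 2)
  expect_true(all(abs(cl$mean_dose[cl$n_years == 2] - 2) < 1e-12))
})

test_that("monthly stats equal a brute-force per-month summary of the day-entries", {
  s <- make_multiyear_series(2004:2009, seed = 8)
  cl <- build_climatology(s)
  ms <- monthly_stats(cl)
  expect_equal(nrow(ms), 12)
  oracle <- tapply(cl$mean_dose, cl$month, mean)
  expect_equal(ms$mean[order(ms$month)], as.numeric(oracle))
  oracle_sd <- tapply(cl$mean_dose, cl$month, stats::sd)
  expect_equal(ms$sd[order(ms$month)], as.numeric(oracle_sd))
  # constant climatology: every month mean c, SD 0
  cl2 <- cl
  cl2$mean_dose <- 3.5
  ms2 <- monthly_stats(cl2)
  expect_true(all(ms2$mean == 3.5) && all(ms2$sd == 0))
})

test_that("annual statistics conserve the cumulative-dose identity", {
  s <- make_multiyear_series(2004:2009, seed = 17)
  cl <- build_climatology(s)
  an <- annual_stats(cl)
  expect_equal(an$cumulative, 365 * an$mean, tolerance = 1e-12)
  # day-weighted inversion of own monthly stats equals the annual mean
  expect_equal(annual_mean_from_monthly(monthly_stats(cl)), an$mean,
               tolerance = 1e-12)
  # constant climatology
  cl$mean_dose <- 2
  expect_equal(unlist(annual_stats(cl)[c("mean", "cumulative")]),
               c(mean = 2, cumulative = 730))
  expect_equal(annual_mean_from_monthly(rep(2, 12)), 2)
})

test_that("packaged capital table reproduces its own printed annual statistics", {
  t1 <- load_capital_table()
  expect_equal(nrow(t1), 46)
  ath <- capital_monthly_means("Athens", t1)
  expect_equal(ath$mean[7], 10.02)
  expect_equal(ath$mean[12], 0.77)
  # day-weighted annual means against the printed annual column
  for (city in t1$city) {
    recomputed <- annual_mean_from_monthly(capital_monthly_means(city, t1))
    printed <- t1$annual_mean[t1$city == city]
    expect_lt(abs(recomputed - printed), 0.01)
  }
  expect_error(capital_monthly_means("Atlantis", t1), "unknown city")
})

test_that("peak/trough fold ratio matches the printed seasonal contrasts", {
  t1 <- load_capital_table()
  ath <- peak_trough_ratio(capital_monthly_means("Athens", t1))
  expect_equal(round(ath$fold), 13)
  expect_equal(ath$peak_month, 7)
  expect_equal(ath$trough_month, 12)
  # London's printed 50-fold contrast is July vs December (its absolute
  # peak month is June, slightly higher still)
  lon <- capital_monthly_means("London", t1)
  expect_equal(round(lon$mean[7] / lon$mean[12]), 50)
  expect_equal(peak_trough_ratio(lon)$peak_month, 6)
  expect_equal(peak_trough_ratio(rep(4, 12))$fold, 1)
  expect_warning(z <- peak_trough_ratio(c(0, rep(1, 11))), "infinite")
  expect_identical(z$fold, Inf)
})

test_that("vitamin D winter counts strictly-below-threshold days and is monotone in threshold", {
  s <- make_multiyear_series(2004:2006, noise_sd = 0, seed = 1)
  cl <- build_climatology(s)
  w <- vitamin_d_winter(cl, threshold = 1)
  oracle <- sum(seasonal_dose(1:365) < 1)
  expect_equal(w$duration_days, oracle)
  expect_equal(nrow(w$below_days), w$duration_days)
  # all above / all below
  cl2 <- cl; cl2$mean_dose <- 2
  expect_equal(vitamin_d_winter(cl2)$duration_days, 0)
  cl2$mean_dose <- 0.5
  expect_equal(vitamin_d_winter(cl2)$duration_days, 365)
  # boundary days equal to the threshold count as synthesis days
  cl2$mean_dose <- 1
  expect_equal(vitamin_d_winter(cl2, threshold = 1)$duration_days, 0)
  # monotone non-increasing in threshold
  durations <- vapply(c(0.5, 1, 2, 4),
                      function(th) vitamin_d_winter(cl, th)$duration_days,
                      numeric(1))
  expect_true(all(diff(durations) >= 0))
})
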