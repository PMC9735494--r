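# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Michalsky (1988) approximate solar ephemeris: zenith angle in degrees
# for a latitude/longitude and a UTC POSIXct instant.
michalsky_zenith <- function(lat, lon, instant) {
  instant <- as.POSIXct(instant, tz = "UTC")
  jd <- as.numeric(instant) / 86400 + 2440587.5
  n <- jd - 2451545.0
  mnlong <- (280.460 + 0.9856474 * n) %% 360
  mnanom <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %%
               360) * pi / 180
  oblqec <- (23.439 - 0.0000004 * n) * pi / 180
  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  dec <- asin(sin(oblqec) * sin(eclong))
  hour_ut <- (as.numeric(instant) %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * (jd - 2451545.0 - hour_ut / 24) +
             hour_ut * 1.0027379) %% 24
  lmst <- ((gmst + lon / 15) %% 24) * 15 * pi / 180
  ha <- lmst - ra
  latr <- lat * pi / 180
  el <- asin(sin(dec) * sin(latr) + cos(dec) * cos(latr) * cos(ha))
  90 - el * 180 / pi
}

# Closed-form OLS via normal equations, with the slope t-test assembled
# from scratch.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  r2 <- 1 - sse / syy
  se <- sqrt(sse / (n - 2) / sxx)
  t <- slope / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2,
       p_value = p, se = se)
}

# Quick builder for a daily series from a dose vector (contiguous days).
make_series <- function(dose, start = as.Date("2004-01-01"),
                        loc = geo_location("TestSite", 50, 10, 100),
                        flag = NULL) {
  dates <- seq(start, by = "day", length.out = length(dose))
  if (is.null(flag)) flag <- ifelse(is.na(dose), "missing", "measured")
  duvb_series(loc, tibble::tibble(date = dates, dose = dose, flag = flag))
}

# Smooth seasonal dose curve (kJ/m2) by day-of-year: sinusoid with summer
# peak around day 172, floored at near-zero in winter.
seasonal_dose <- function(doy, peak = 6, trough = 0.05) {
  mid <- (peak + trough) / 2
  amp <- (peak - trough) / 2
  mid - amp * cos(2 * pi * (doy - 172 + 182.5) / 365)
}

# Multi-year synthetic series on the seasonal curve with multiplicative
# lognormal noise; no spectral simulator involved.
make_multiyear_series <- function(years = 2004:2021, noise_sd = 0.2,
                                  seed = 42,
                                  loc = geo_location("TestSite", 50, 10, 100)) {
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  leap <- (as.integer(strftime(dates, "%Y")) %% 4) == 0
  doy[leap & doy >= 60] <- doy[leap & doy >= 60] - 1L
  dose <- seasonal_dose(doy) * exp(stats::rnorm(length(dates), 0, noise_sd))
  duvb_series(loc, tibble::tibble(date = dates, dose = dose,
                                  flag = "measured"))
}
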