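# Synthetic stand-in for a satellite daily D-UVB extract: multi-year daily
# series with an SZA-driven seasonal cycle, multiplicative day-to-day cloud
# noise, blackout days, and matched synthetic 25(OH)D study tables with
# known ground truth, so every pipeline stage is testable without any
# download.

#' A selection of European capitals as geo_locations
#'
#' Coordinates and rough surface elevations for capitals spanning the
#' 35-64 degree latitude range of the European climatology.
#'
#' @param names Optional character vector to subset (default: all).
#' @return A named list of [geo_location()] objects.
#' @export
european_capitals <- function(names = NULL) {
  tab <- list(
    Nicosia   = c(35.17, 33.36, 150),
    Athens    = c(37.98, 23.73, 100),
    Madrid    = c(40.42, -3.70, 650),
    Rome      = c(41.90, 12.50, 40),
    Kiev      = c(50.45, 30.52, 170),
    Prague    = c(50.08, 14.44, 230),
    Brussels  = c(50.80, 4.36, 50),
    London    = c(51.51, -0.13, 25),
    Dublin    = c(53.35, -6.26, 20),
    Vilnius   = c(54.69, 25.28, 110),
    Oslo      = c(59.91, 10.75, 20),
    Reykjavik = c(64.15, -21.94, 40)
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(tab))
    if (length(missing))
      stop("unknown capital(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    tab <- tab[names]
  }
  lapply(stats::setNames(base::names(tab), base::names(tab)), function(nm) {
    v <- tab[[nm]]
    geo_location(nm, v[1], v[2], v[3])
  })
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults mirror the conditions of the 18-year satellite record the
#' generator emulates: years 2004-2021, a spring-peaked ozone cycle around
#' a European mid-latitude mean, day-to-day multiplicative cloud noise
#' with more variance in summer, and a few percent of blackout days.
#'
#' @param locations Named list of [geo_location()]s. Default: Athens,
#'   Dublin, Oslo and Reykjavik (a south-to-north ladder).
#' @param years Integer vector of calendar years. Default 2004:2021.
#' @param ozone_mean_du Mean total column ozone (DU). Default 330.
#' @param ozone_amplitude_du Annual ozone amplitude (DU), peaking in early
#'   April. Default 40.
#' @param cloud_mean Mean cloud modification factor on the (0.2, 1\] scale.
#'   Default 0.72.
#' @param cloud_conc_winter,cloud_conc_summer Beta concentration of the
#'   cloud factor in deep winter / at the clear-sky dose peak; the summer
#'   value is smaller so that day-to-day dose varies most when there is
#'   most to lose. Defaults 30 and 6.
#' @param blackout_rate Per-day probability of a blackout (missing) day, in
#'   \[0, 1). Default 0.03.
#' @param seed Master integer seed; every location derives its own stream
#'   from it, so adding a location never perturbs the others.
#' @param n_studies,study_months,true_slope,noise_sd Study-table spec: the
#'   number of synthetic studies, the months each observes, the generative
#'   slope (nmol/L per kJ m-2 of CW-D-UVB; default 0.126) and the residual
#'   SD of monthly mean 25(OH)D (nmol/L; default 8).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(locations = european_capitals(
                              c("Athens", "Dublin", "Oslo", "Reykjavik")),
                            years = 2004:2021,
                            ozone_mean_du = 330,
                            ozone_amplitude_du = 40,
                            cloud_mean = 0.72,
                            cloud_conc_winter = 30,
                            cloud_conc_summer = 6,
                            blackout_rate = 0.03,
                            seed = 1L,
                            n_studies = 8L,
                            study_months = 1:12,
                            true_slope = 0.126,
                            noise_sd = 8) {
  stopifnot(length(locations) >= 1,
            all(vapply(locations, inherits, TRUE, "geo_location")))
  if (blackout_rate < 0 || blackout_rate >= 1)
    stop("blackout_rate must be in [0, 1)", call. = FALSE)
  if (cloud_mean <= 0.2 || cloud_mean > 1)
    stop("cloud_mean must be in (0.2, 1]", call. = FALSE)
  if (!3 %in% study_months)
    stop("study_months must include March (the delta reference)", call. = FALSE)
  structure(
    list(locations = locations, years = as.integer(years),
         ozone_mean_du = ozone_mean_du,
         ozone_amplitude_du = ozone_amplitude_du,
         cloud_mean = cloud_mean,
         cloud_conc_winter = cloud_conc_winter,
         cloud_conc_summer = cloud_conc_summer,
         blackout_rate = blackout_rate, seed = as.integer(seed),
         n_studies = as.integer(n_studies), study_months = study_months,
         true_slope = true_slope, noise_sd = noise_sd),
    class = "scenario_config"
  )
}

# stable per-location stream seed below 2^31
location_seed <- function(master_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(master_seed) %% 100000L) * 20011L + (h %% 20011L)
}

# spring-peaked annual ozone cycle (DU) over day of year 1..365
ozone_cycle <- function(cfg) {
  doy <- seq_len(365)
  cfg$ozone_mean_du +
    cfg$ozone_amplitude_du * cos(2 * pi * (doy - 95) / 365)
}

#' Generate synthetic multi-year daily D-UVB series
#'
#' For each location: the 365-day clear-sky diurnal dose cycle (fixed
#' spring-peaked ozone, 5-min integration) is expanded over the configured
#' years; on days where geostationary cloud retrieval would be unavailable
#' (noon SZA above 78 degrees) the clear-sky dose is multiplied by the
#' fixed 0.7 winter cloud factor, otherwise by a Beta-distributed daily
#' cloud factor rescaled to (0.2, 1\] whose variance grows with the
#' clear-sky dose (day-to-day variation is largest in summer); finally a
#' fraction of days becomes blackout (missing). Fully reproducible under
#' the master seed, with one independent stream per location.
#'
#' @param cfg A [scenario_config()].
#' @param step Diurnal integration step in minutes (default 5).
#' @return A named list of [duvb_series()], one per location.
#' @export
generate_series <- function(cfg, step = 5) {
  stopifnot(inherits(cfg, "scenario_config"))
  params <- atmosphere_params(total_column_ozone = cfg$ozone_mean_du)
  o3 <- ozone_cycle(cfg)
  spectrum <- load_action_spectrum()
  lapply(cfg$locations, function(loc) {
    cycle <- clearsky_annual_cycle(loc, params, spectrum, step = step,
                                   ozone_by_day = o3)
    dates <- seq(as.Date(sprintf("%d-01-01", min(cfg$years))),
                 as.Date(sprintf("%d-12-31", max(cfg$years))), by = "day")
    doy <- day_of_year_365(dates)
    clear <- cycle$dose[doy]
    set.seed(location_seed(cfg$seed, loc$name))
    # cloud factor: Beta on (0.2, 1], less concentrated where the
    # clear-sky dose (hence the absolute loss to cloud) is larger
    mu <- (cfg$cloud_mean - 0.2) / 0.8
    rel <- clear / max(cycle$dose)
    conc <- cfg$cloud_conc_winter -
      (cfg$cloud_conc_winter - cfg$cloud_conc_summer) * rel
    cmf <- 0.2 + 0.8 * stats::rbeta(length(dates), mu * conc,
                                    (1 - mu) * conc)
    gap <- noon_sza(loc, dates) > 78
    dose <- ifelse(gap, clear * 0.7, clear * cmf)
    flag <- ifelse(gap, "winter_factor", "measured")
    blackout <- stats::runif(length(dates)) < cfg$blackout_rate
    dose[blackout] <- NA_real_
    flag[blackout] <- "missing"
    duvb_series(loc, tibble::tibble(date = dates, dose = dose, flag = flag))
  })
}

#' Generate synthetic monthly 25(OH)D study tables with known ground truth
#'
#' Each synthetic study is assigned a city (cycling through the CW
#' library), a cohort class, and a study-level baseline; its monthly mean
#' is baseline + true_slope * (CW(m) - CW(3)) + Normal(0, noise_sd) noise,
#' the generative twin of the delta-versus-March linkage model.
#'
#' @param cfg A [scenario_config()].
#' @param cw_library Named list (or long data frame) of monthly CW-D-UVB
#'   profiles per city, as accepted by [resolve_city_cw()].
#' @return A list with `records` (a study table as in [read_study_table()])
#'   and `truth` (`true_slope`, per-study baselines).
#' @export
generate_study_tables <- function(cfg, cw_library) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.data.frame(cw_library))
    cities <- unique(cw_library$city)
  else
    cities <- names(cw_library)
  set.seed(cfg$seed + 104729L)
  baselines <- stats::rnorm(cfg$n_studies, mean = 55, sd = 10)
  records <- lapply(seq_len(cfg$n_studies), function(i) {
    city <- cities[(i - 1) %% length(cities) + 1]
    cw <- resolve_city_cw(city, cw_library)
    months <- sort(unique(cfg$study_months))
    mu <- baselines[i] + cfg$true_slope *
      (cw$cw_mean[months] - cw$cw_mean[3])
    tibble::tibble(
      study_id = sprintf("synth%02d", i),
      cohort_class = "A",
      city_rule = city,
      month = months,
      mean_25ohd_nmol_l = pmax(mu + stats::rnorm(length(months),
                                                 sd = cfg$noise_sd), 1)
    )
  })
  list(records = dplyr::bind_rows(records),
       truth = list(true_slope = cfg$true_slope, baselines = baselines))
}
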