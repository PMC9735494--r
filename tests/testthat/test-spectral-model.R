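test_that("action spectrum satisfies its shape invariants", {
  sp <- load_action_spectrum()
  expect_identical(sp$wavelengths, 290:315)
  expect_equal(max(sp$weights), 1)
  peak <- sp$wavelengths[which.max(sp$weights)]
  expect_gte(peak, 295)
  expect_lte(peak, 298)
  expect_true(all(sp$weights >= 0 & sp$weights <= 1))
  expect_lt(sp$weights[sp$wavelengths == 315], 0.01)
  expect_gt(sp$weights[sp$wavelengths == 290],
            sp$weights[sp$wavelengths == 315])
})

test_that("irradiance is zero below the horizon and errors on bad ozone", {
  p <- atmosphere_params()
  expect_identical(clearsky_weighted_irradiance(c(90, 95, 120), p),
                   c(0, 0, 0))
  expect_error(atmosphere_params(total_column_ozone = 0), "ozone")
  expect_error(atmosphere_params(total_column_ozone = -10), "ozone")
})

test_that("with no extinction the overhead irradiance is the bare weighted integral", {
  p <- atmosphere_params(surface_albedo = 0)
  p$ozone_cross_section[] <- 0
  p$rayleigh_optical_depth[] <- 0
  sp <- load_action_spectrum()
  got <- clearsky_weighted_irradiance(0, p, sp)
  integrand <- p$extraterrestrial_spectrum * sp$weights
  wtrap <- rep(1, length(integrand)); wtrap[c(1, length(wtrap))] <- 0.5
  expect_equal(got, sum(wtrap * integrand), tolerance = 1e-12)
})

test_that("irradiance is monotone non-increasing in ozone and Rayleigh depth", {
  sp <- load_action_spectrum()
  szas <- seq(0, 85, by = 5)
  base <- atmosphere_params(total_column_ozone = 300)
  for (mult in c(1.5, 2, 4)) {
    more <- atmosphere_params(total_column_ozone = 300 * mult)
    expect_true(all(clearsky_weighted_irradiance(szas, more, sp) <=
                      clearsky_weighted_irradiance(szas, base, sp)))
  }
  thick <- base
  thick$rayleigh_optical_depth <- base$rayleigh_optical_depth * 2
  expect_true(all(clearsky_weighted_irradiance(szas, thick, sp) <=
                    clearsky_weighted_irradiance(szas, base, sp)))
})

test_that("diurnal dose scales exactly with the cloud factor and vanishes in polar night", {
  loc <- geo_location("ath", 37.98, 23.73, 100)
  d <- as.Date("2020-06-21")
  full <- diurnal_duvb_dose(loc, d, atmosphere_params())$dose
  half <- diurnal_duvb_dose(
    loc, d, atmosphere_params(cloud_modification_factor = 0.5))$dose
  expect_equal(half, full / 2, tolerance = 1e-12)
  polar <- geo_location("n", 89, 0)
  expect_identical(
    diurnal_duvb_dose(polar, as.Date("2020-12-21"), atmosphere_params())$dose,
    0)
})

test_that("mid-latitude summer dose dominates winter dose more than five-fold", {
  loc <- geo_location("ath", 38, 23.73, 100)
  p <- atmosphere_params()
  june <- diurnal_duvb_dose(loc, as.Date("2020-06-21"), p)$dose
  dec <- diurnal_duvb_dose(loc, as.Date("2020-12-21"), p)$dose
  expect_gt(june, 5 * dec)
})

test_that("refining the time step from 5 to 1 minutes moves the dose by under 0.5 percent", {
  loc <- geo_location("dub", 53.35, -6.26, 20)
  p <- atmosphere_params()
  for (d in as.Date(c("2020-03-20", "2020-06-21", "2020-12-21"))) {
    d5 <- diurnal_duvb_dose(loc, d, p, step = 5)$dose
    d1 <- diurnal_duvb_dose(loc, d, p, step = 1)$dose
    expect_lt(abs(d5 - d1) / d1, 0.005)
  }
})

test_that("clear-sky dose is a function of solar declination: equal-declination days agree within 2 percent", {
  # under a fixed atmosphere the dose depends on the date only through the
  # sun's declination, so days on either flank of the solstice with equal
  # declination must carry (near-)equal dose
  loc <- geo_location("mid", 45, 0, 0)
  p <- atmosphere_params()
  cyc <- clearsky_annual_cycle(loc, p, step = 10)
  decl <- solar_declination(cyc$doy)
  solstice <- which.max(decl)
  for (k in c(10, 30, 60)) {
    d1 <- solstice - k
    # mirror day: same declination on the descending flank
    after <- (solstice + 1):365
    d2 <- after[which.min(abs(decl[after] - decl[d1]))]
    a <- cyc$dose[d1]
    b <- cyc$dose[d2]
    expect_lt(abs(a - b) / max(a, b), 0.02)
  }
})

test_that("on a June date the dose falls with latitude on the winter-hemisphere side", {
  p <- atmosphere_params()
  doses <- vapply(seq(0, 66, by = 11), function(lat)
    diurnal_duvb_dose(geo_location("x", lat, 0), as.Date("2020-12-21"),
                      p)$dose, numeric(1))
  expect_true(all(diff(doses) < 0))
})

test_that("atmosphere config round-trips through the key-value reader", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# scenario", "total_column_ozone = 285",
               "cloud_modification_factor = 0.8",
               "surface_albedo: 0.1"), path)
  p <- read_atmosphere_config(path)
  expect_equal(p$total_column_ozone, 285)
  expect_equal(p$cloud_modification_factor, 0.8)
  expect_equal(p$surface_albedo, 0.1)
  writeLines("nonsense_key = 2", path)
  expect_error(read_atmosphere_config(path), "unknown config key")
})

test_that("action spectrum exports as a two-column CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_action_spectrum(load_action_spectrum(), path)
  got <- utils::read.csv(path)
  expect_identical(names(got), c("wavelength_nm", "weight"))
  expect_equal(nrow(got), 26)
  expect_equal(max(got$weight), 1)
})
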