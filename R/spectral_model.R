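# Clear-sky vitamin-D-weighted irradiance and diurnal dose.
#
# Deliberately simplified two-extinction (ozone + Rayleigh) plane-parallel
# model with the Kasten-Young airmass. It emulates the *structure* of a
# satellite daily-dose product (seasonal cycle, latitude gradient, ozone
# sensitivity); its absolute values are never asserted against any
# published product.

# 1-nm wavelength grid spanning the vitamin-D action range
DUVB_GRID_NM <- 290:315

# Anchor tables, interpolated to the 1-nm grid at load time. Values are
# reconstructions of standard reference shapes (top-of-atmosphere solar UV,
# Hartley-Huggins ozone absorption, previtamin-D3 action spectrum), smooth
# and monotone where the originals are; adequate for a structural simulator.
.e0_anchor <- data.frame(
  nm = c(280, 285, 290, 295, 300, 305, 310, 315, 320),
  irr = c(0.22, 0.32, 0.48, 0.56, 0.53, 0.61, 0.69, 0.73, 0.78)  # W m-2 nm-1
)
# Huggins-band cross-sections at stratospheric temperature (~228 K),
# where most ozone absorption occurs; colder values are 20-30% below the
# room-temperature tables in the 305-315 nm tail.
.o3_anchor <- data.frame(
  nm = c(280, 285, 290, 295, 300, 305, 310, 315, 320),
  xs = c(3.9e-18, 2.5e-18, 1.40e-18, 6.2e-19, 2.9e-19,
         1.1e-19, 4.5e-20, 1.8e-20, 7.0e-21)  # cm2 molecule-1
)
.act_anchor <- data.frame(
  nm = c(290, 292, 294, 295, 297, 298, 300, 302, 305,
         308, 310, 313, 315),
  w = c(0.72, 0.83, 0.95, 1.00, 1.00, 0.97, 0.78, 0.52, 0.19,
        0.060, 0.022, 0.006, 0.0025)
)

# molecules per cm2 in one Dobson unit
.DU_COLUMN <- 2.687e16

#' Vitamin D action spectrum
#'
#' Relative effectiveness of monochromatic UV for cutaneous previtamin D3
#' synthesis on a 1-nm grid over 290--315 nm, normalised to a maximum of 1
#' (attained at 295--297 nm). The table is a smooth reconstruction of the
#' standard published action-spectrum shape.
#'
#' @return A list of class `action_spectrum` with `wavelengths` (nm) and
#'   `weights` (dimensionless, max 1).
#' @examples
#' sp <- load_action_spectrum()
#' sp$wavelengths[which.max(sp$weights)]
#' @export
load_action_spectrum <- function() {
  w <- exp(stats::approx(.act_anchor$nm, log(.act_anchor$w),
                         xout = DUVB_GRID_NM)$y)
  w <- w / max(w)
  structure(list(wavelengths = DUVB_GRID_NM, weights = w),
            class = "action_spectrum")
}

#' Write an action spectrum as two-column CSV
#'
#' @param spectrum An [load_action_spectrum()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_action_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "action_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelengths, weight = spectrum$weights),
    path, row.names = FALSE)
  invisible(path)
}

#' Atmospheric parameters for the clear-sky model
#'
#' Bundles the per-wavelength tables and the scalar modifiers used by
#' [clearsky_weighted_irradiance()]. Per-nm tables share the action-spectrum
#' grid (290--315 nm at 1 nm).
#'
#' @param total_column_ozone Total column ozone in Dobson units (> 0).
#'   Default 300 DU, a typical European mid-latitude annual mean.
#' @param cloud_modification_factor Multiplicative attenuation of the
#'   clear-sky dose by cloud, in (0, 1.2\]. Default 1 (clear sky).
#' @param surface_albedo Surface UV albedo in \[0, 1\]; enters as a simple
#'   enhancement 1 + 0.25 * albedo. Default 0.05 (vegetation/soil).
#' @param elevation_scaling Fractional dose increase per km of surface
#'   elevation (>= 0). Default 0.08 (about +8 percent per km).
#' @param rayleigh_scaling Effective-extinction scaling of the Rayleigh
#'   optical depth, in (0, 1\]. Rayleigh scattering is not pure loss: part
#'   of the scattered flux reaches the ground as diffuse irradiance, which
#'   a single Beer-Lambert extinction term overstates. The transmission
#'   uses the scaled depth `rayleigh_scaling * tau_R`; 0.5 (default) sits
#'   between pure extinction (1) and a fully transparent scattering
#'   atmosphere (toward 0).
#'
#' @return A list of class `atmosphere_params` including the per-nm
#'   `extraterrestrial_spectrum` (W m-2 nm-1), `ozone_cross_section`
#'   (DU-1) and `rayleigh_optical_depth` tables on `wavelengths`.
#' @export
atmosphere_params <- function(total_column_ozone = 300,
                              cloud_modification_factor = 1,
                              surface_albedo = 0.05,
                              elevation_scaling = 0.08,
                              rayleigh_scaling = 0.5) {
  if (!is.finite(total_column_ozone) || total_column_ozone <= 0)
    stop("total_column_ozone must be > 0 DU", call. = FALSE)
  if (cloud_modification_factor <= 0 || cloud_modification_factor > 1.2)
    stop("cloud_modification_factor must be in (0, 1.2]", call. = FALSE)
  if (surface_albedo < 0 || surface_albedo > 1)
    stop("surface_albedo must be in [0, 1]", call. = FALSE)
  if (elevation_scaling < 0)
    stop("elevation_scaling must be >= 0", call. = FALSE)
  if (rayleigh_scaling <= 0 || rayleigh_scaling > 1)
    stop("rayleigh_scaling must be in (0, 1]", call. = FALSE)
  nm <- DUVB_GRID_NM
  e0 <- stats::approx(.e0_anchor$nm, .e0_anchor$irr, xout = nm)$y
  # ozone cross-section falls near-exponentially; interpolate in log space,
  # then convert cm2/molecule to optical depth per Dobson unit
  xs <- exp(stats::approx(.o3_anchor$nm, log(.o3_anchor$xs), xout = nm)$y)
  o3_per_du <- xs * .DU_COLUMN
  rayleigh <- 0.008735 * (nm / 1000)^(-4.08)
  structure(
    list(wavelengths = nm,
         extraterrestrial_spectrum = e0,
         ozone_cross_section = o3_per_du,
         rayleigh_optical_depth = rayleigh,
         total_column_ozone = total_column_ozone,
         cloud_modification_factor = cloud_modification_factor,
         surface_albedo = surface_albedo,
         elevation_scaling = elevation_scaling,
         rayleigh_scaling = rayleigh_scaling),
    class = "atmosphere_params"
  )
}

#' Read atmosphere parameters from a key-value config file
#'
#' Plain-text `key = value` lines (comments with `#`); recognised keys are
#' the scalar arguments of [atmosphere_params()].
#'
#' @param path Config file path.
#' @return An [atmosphere_params()] object.
#' @export
read_atmosphere_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("unparseable config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  allowed <- c("total_column_ozone", "cloud_modification_factor",
               "surface_albedo", "elevation_scaling", "rayleigh_scaling")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(atmosphere_params, as.list(vals))
}

# Kasten-Young (1989) relative optical airmass, z in degrees < 90
airmass_kasten_young <- function(sza) {
  1 / (cos(deg2rad(sza)) + 0.50572 * (96.07995 - sza)^(-1.6364))
}

#' Clear-sky vitamin-D-weighted surface irradiance
#'
#' Plane-parallel Beer-Lambert transmission with ozone absorption and
#' Rayleigh extinction, weighted by the action spectrum and integrated over
#' wavelength (trapezoid on the 1-nm grid). The transmitted fraction per
#' wavelength is exp(-(sigma_O3 * ozone + r * tau_R) * m(SZA)) with the
#' Kasten-Young airmass m and the effective Rayleigh scaling r
#' (`rayleigh_scaling`), which credits the scattered flux that still
#' reaches the ground as diffuse irradiance. The weighted integral is
#' multiplied by cos(SZA) and the elevation and albedo enhancements.
#'
#' @param sza Solar zenith angle(s) in degrees, in \[0, 180\]. Values at or
#'   beyond 90 return 0 (sun below the horizon).
#' @param params An [atmosphere_params()] object.
#' @param spectrum An [load_action_spectrum()] object (or compatible).
#' @param elevation_km Surface elevation in km used for the elevation
#'   enhancement. Default 0.
#'
#' @return Weighted irradiance in W m-2 (vector along `sza`).
#' @export
clearsky_weighted_irradiance <- function(sza, params,
                                         spectrum = load_action_spectrum(),
                                         elevation_km = 0) {
  stopifnot(inherits(params, "atmosphere_params"))
  if (any(!is.finite(sza)) || any(sza < 0) || any(sza > 180))
    stop("sza must be in [0, 180] degrees", call. = FALSE)
  if (!identical(as.integer(spectrum$wavelengths),
                 as.integer(params$wavelengths)))
    stop("spectrum and params wavelength grids differ", call. = FALSE)
  out <- numeric(length(sza))
  up <- sza < 90
  if (!any(up)) return(out)
  z <- sza[up]
  m <- airmass_kasten_young(z)
  tau <- params$ozone_cross_section * params$total_column_ozone +
    params$rayleigh_scaling * params$rayleigh_optical_depth
  # rows = wavelengths, cols = instants
  trans <- exp(-outer(tau, m))
  integrand <- trans * (params$extraterrestrial_spectrum * spectrum$weights)
  # trapezoid on the uniform 1-nm grid
  wtrap <- rep(1, length(params$wavelengths))
  wtrap[c(1, length(wtrap))] <- 0.5
  band <- as.numeric(crossprod(wtrap, integrand))
  scale <- (1 + params$elevation_scaling * elevation_km) *
    (1 + 0.25 * params$surface_albedo)
  out[up] <- band * cos(deg2rad(z)) * scale
  out
}

#' Diurnal vitamin-D-weighted UVB dose
#'
#' Integrates the clear-sky weighted irradiance on a fixed-step grid from
#' sunrise to sunset and multiplies by the cloud modification factor,
#' returning the daily dose in kJ m-2. Zero on polar night; on midnight-sun
#' days the full 24 h around local solar noon are integrated.
#'
#' @param loc A [geo_location()].
#' @param date A single `Date` (or coercible).
#' @param params An [atmosphere_params()] object.
#' @param spectrum An action spectrum.
#' @param step Integration step in minutes (<= 30). Default 5.
#'
#' @return A one-row tibble (`date`, `dose` in kJ m-2).
#' @examples
#' ath <- geo_location("Athens", 37.98, 23.73, 100)
#' diurnal_duvb_dose(ath, as.Date("2020-06-21"), atmosphere_params())
#' @export
diurnal_duvb_dose <- function(loc, date, params,
                              spectrum = load_action_spectrum(), step = 5) {
  stopifnot(inherits(loc, "geo_location"), inherits(params, "atmosphere_params"))
  if (step <= 0 || step > 30) stop("step must be in (0, 30] minutes", call. = FALSE)
  date <- as.Date(date)
  win <- daylight_window(loc, date)
  if (win$status == "no_daylight")
    return(tibble::tibble(date = date, dose = 0))
  if (win$status == "no_night") {
    noon <- solar_noon_utc(loc, date)
    t0 <- noon - 12 * 3600
    t1 <- noon + 12 * 3600
  } else {
    t0 <- win$sunrise
    t1 <- win$sunset
  }
  times <- seq(from = t0, to = t1, by = step * 60)
  sza <- solar_zenith_angle(loc, times)
  irr <- clearsky_weighted_irradiance(sza, params, spectrum,
                                      elevation_km = loc$elevation / 1000)
  dose_kj <- sum(irr) * step * 60 / 1000 * params$cloud_modification_factor
  tibble::tibble(date = date, dose = dose_kj)
}

#' Clear-sky dose for each day of a 365-day year
#'
#' Convenience wrapper computing the diurnal clear-sky dose for every
#' (month, day) of a non-leap calendar year; the workhorse behind the
#' synthetic series generator and latitude-gradient analyses.
#'
#' @inheritParams diurnal_duvb_dose
#' @param ozone_by_day Optional numeric vector of length 365 giving total
#'   column ozone (DU) per day of year; overrides `params$total_column_ozone`.
#' @return A tibble with `doy` (1..365), `month`, `day`, `dose` (kJ m-2).
#' @export
clearsky_annual_cycle <- function(loc, params,
                                  spectrum = load_action_spectrum(),
                                  step = 5, ozone_by_day = NULL) {
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  if (!is.null(ozone_by_day) && length(ozone_by_day) != 365)
    stop("ozone_by_day must have length 365", call. = FALSE)
  dose <- vapply(seq_along(dates), function(i) {
    p <- params
    if (!is.null(ozone_by_day)) {
      p <- atmosphere_params(
        total_column_ozone = ozone_by_day[i],
        cloud_modification_factor = params$cloud_modification_factor,
        surface_albedo = params$surface_albedo,
        elevation_scaling = params$elevation_scaling,
        rayleigh_scaling = params$rayleigh_scaling)
    }
    diurnal_duvb_dose(loc, dates[i], p, spectrum, step)$dose
  }, numeric(1))
  tibble::tibble(
    doy = seq_len(365),
    month = as.integer(strftime(dates, "%m")),
    day = as.integer(strftime(dates, "%d")),
    dose = dose
  )
}
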