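# Daily dose series container, CSV dialect and the two missing-data rules:
# blackout-day imputation by the same-calendar-day multi-year mean, and the
# fixed 0.7 cloud factor on high-latitude winter days without cloud
# retrieval (noon SZA above 78 degrees).

SERIES_FLAGS <- c("measured", "blackout_imputed", "winter_factor", "missing")

#' Construct a daily dose series
#'
#' @param location A [geo_location()].
#' @param records A data frame with columns `date` (Date, strictly
#'   increasing, no duplicates), `dose` (kJ m-2, NA allowed) and `flag`
#'   (one of "measured", "blackout_imputed", "winter_factor", "missing").
#'
#' @return An object of class `duvb_series`.
#' @export
duvb_series <- function(location, records) {
  stopifnot(inherits(location, "geo_location"))
  records <- tibble::as_tibble(records)
  if (!all(c("date", "dose", "flag") %in% names(records)))
    stop("records need columns date, dose, flag", call. = FALSE)
  records$date <- as.Date(records$date)
  if (anyNA(records$date))
    stop("unparseable dates in records", call. = FALSE)
  if (is.unsorted(records$date, strictly = TRUE))
    stop("dates must be strictly increasing (no duplicates)", call. = FALSE)
  if (!all(records$flag %in% SERIES_FLAGS))
    stop("flags must be one of: ", paste(SERIES_FLAGS, collapse = ", "),
         call. = FALSE)
  if (any(!is.na(records$dose) & records$dose < 0))
    stop("doses must be >= 0 where present", call. = FALSE)
  if (any(records$flag == "missing" & !is.na(records$dose)))
    stop("records flagged missing must have NA dose", call. = FALSE)
  structure(list(location = location, records = records),
            class = "duvb_series")
}

#' @export
print.duvb_series <- function(x, ...) {
  cat(sprintf("<duvb_series> %s: %d days (%s to %s), %d missing\n",
              x$location$name, nrow(x$records),
              min(x$records$date), max(x$records$date),
              sum(x$records$flag == "missing")))
  invisible(x)
}

#' Read a daily D-UVB dose series from CSV
#'
#' Canonical dialect: headered CSV with columns `date` (YYYY-MM-DD),
#' `dose_kjm2` (empty for missing days) and optional `flag` (defaults to
#' "measured"; empty dose forces "missing"). Unparseable rows abort with
#' their line numbers.
#'
#' @param path File path.
#' @param location A [geo_location()] for the series.
#' @return A [duvb_series()].
#' @export
read_daily_series <- function(path, location) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("date", "dose_kjm2") %in% names(raw)))
    stop("expected columns date, dose_kjm2[, flag]", call. = FALSE)
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad))
    stop("unparseable date on data line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dose_chr <- trimws(raw$dose_kjm2)
  dose <- suppressWarnings(as.numeric(dose_chr))
  bad <- which(nzchar(dose_chr) & is.na(dose))
  if (length(bad))
    stop("unparseable dose on data line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  flag <- if ("flag" %in% names(raw)) trimws(raw$flag) else
    rep("", nrow(raw))
  flag[!nzchar(flag)] <- "measured"
  flag[is.na(dose)] <- "missing"
  duvb_series(location,
              tibble::tibble(date = dates, dose = dose, flag = flag))
}

#' Write a daily dose series to CSV
#'
#' Inverse of [read_daily_series()]; a read-write-read round trip is the
#' identity on records.
#'
#' @param series A [duvb_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  stopifnot(inherits(series, "duvb_series"))
  out <- data.frame(
    date = format(series$records$date, "%Y-%m-%d"),
    dose_kjm2 = ifelse(is.na(series$records$dose), "",
                       format(series$records$dose, digits = 15,
                              scientific = FALSE, trim = TRUE)),
    flag = series$records$flag
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute blackout days with the same-calendar-day multi-year mean
#'
#' Every missing day that has at least one same-(month, day) observation in
#' another year receives the mean of those observations and the flag
#' "blackout_imputed". Feb 29 is only imputed from Feb 29 of other leap
#' years. Measured values are never altered; the operation is idempotent,
#' and because the substitute is the mean, the day-of-year climatology is
#' unchanged by imputation.
#'
#' @param series A [duvb_series()].
#' @return A [duvb_series()] with imputed records; days with no imputation
#'   base stay missing (their count is reported via a message).
#' @export
impute_blackouts <- function(series) {
  stopifnot(inherits(series, "duvb_series"))
  rec <- series$records
  miss <- which(rec$flag == "missing")
  if (!length(miss)) return(series)
  key <- format(rec$date, "%m-%d")
  base_mean <- tapply(rec$dose[rec$flag != "missing"],
                      key[rec$flag != "missing"], mean)
  fill <- base_mean[key[miss]]
  imputable <- !is.na(fill)
  rec$dose[miss[imputable]] <- as.numeric(fill[imputable])
  rec$flag[miss[imputable]] <- "blackout_imputed"
  n_left <- sum(!imputable)
  if (n_left > 0)
    message(n_left, " missing day(s) had no same-calendar-day base and remain missing")
  duvb_series(series$location, rec)
}

#' Days without winter cloud retrieval (noon SZA above a cutoff)
#'
#' Geostationary cloud retrieval fails at large solar zenith angles; this
#' predicate marks the days of a series whose noon SZA exceeds the cutoff.
#'
#' @param series A [duvb_series()].
#' @param cutoff Noon SZA cutoff in degrees. Default 78.
#' @return Logical vector along the series records.
#' @export
sza_gap_days <- function(series, cutoff = 78) {
  stopifnot(inherits(series, "duvb_series"))
  noon_sza(series$location, series$records$date) > cutoff
}

#' Apply the winter cloud factor on retrieval-gap days
#'
#' On days where cloud retrieval is unavailable (by default: noon solar
#' zenith angle above 78 degrees), the dose is multiplied by a fixed mean
#' cloud attenuation factor (default 0.7) and flagged "winter_factor".
#' Other days are untouched.
#'
#' @param series A [duvb_series()].
#' @param factor Attenuation factor in (0, 1\]. Default 0.7.
#' @param gap_predicate Logical vector along the records marking gap days,
#'   or a function of the series returning one. Default [sza_gap_days()].
#' @return A [duvb_series()].
#' @export
apply_winter_cloud_factor <- function(series, factor = 0.7,
                                      gap_predicate = sza_gap_days) {
  stopifnot(inherits(series, "duvb_series"))
  if (!is.finite(factor) || factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]", call. = FALSE)
  gap <- if (is.function(gap_predicate)) gap_predicate(series) else gap_predicate
  if (!is.logical(gap) || length(gap) != nrow(series$records))
    stop("gap_predicate must mark one day per record", call. = FALSE)
  rec <- series$records
  hit <- gap & !is.na(rec$dose)
  rec$dose[hit] <- rec$dose[hit] * factor
  rec$flag[hit] <- "winter_factor"
  duvb_series(series$location, rec)
}
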