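# Descriptive statistics of a multi-year daily dose record: the 365-day
# climatology (leap days omitted), monthly and annual summaries, cumulative
# annual dose, peak/trough fold ratio, and the vitamin D winter duration.

#' Day-of-year climatology of a daily dose series
#'
#' For each of the 365 (month, day) pairs of a non-leap year, the mean and
#' SD of the dose over the available years. Feb 29 records are dropped, so
#' a multi-year record reduces to exactly 365 datapoints. With a single
#' year of data the SD is defined as 0 (with a warning).
#'
#' @param series A [duvb_series()]; missing days are ignored (impute first
#'   if blackout days should contribute).
#' @return A `duvb_climatology`: tibble with `month`, `day`, `mean_dose`,
#'   `sd_dose`, `n_years`, plus the location as attribute `location`.
#' @export
build_climatology <- function(series) {
  stopifnot(inherits(series, "duvb_series"))
  rec <- series$records[series$records$flag != "missing", ]
  if (!nrow(rec)) stop("series has no observed days", call. = FALSE)
  rec$month <- as.integer(format(rec$date, "%m"))
  rec$day <- as.integer(format(rec$date, "%d"))
  rec <- rec[!(rec$month == 2L & rec$day == 29L), ]
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$month, .data$day),
    mean_dose = mean(.data$dose),
    sd_dose = stats::sd(.data$dose),
    n_years = dplyr::n(),
    .groups = "drop"
  )
  if (any(out$n_years == 1L)) {
    warning("some days observed in a single year; their SD is set to 0",
            call. = FALSE)
    out$sd_dose[out$n_years == 1L] <- 0
  }
  out <- dplyr::arrange(out, .data$month, .data$day)
  if (nrow(out) != 365L)
    warning("climatology has ", nrow(out), " day-entries (expected 365)",
            call. = FALSE)
  structure(out, location = series$location,
            class = c("duvb_climatology", class(out)))
}

#' Monthly mean and SD from a climatology
#'
#' Month-level statistics over the day-entries of the climatology: the
#' January mean is the mean of the 31 January day-means, and the SD is the
#' SD of those day-means (matching how multi-year satellite dose tables are
#' summarised from 365 day-of-year means).
#'
#' @param clim A [build_climatology()] result, or any data frame with
#'   `month` and `mean_dose` columns.
#' @return A tibble with `month`, `mean`, `sd` (12 rows).
#' @export
monthly_stats <- function(clim) {
  stopifnot(all(c("month", "mean_dose") %in% names(clim)))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(clim), .data$month),
    mean = mean(.data$mean_dose),
    sd = stats::sd(.data$mean_dose),
    .groups = "drop"
  )
}

#' Annual mean, SD and cumulative dose from a climatology
#'
#' Mean and SD over the 365 day-entries; the cumulative annual dose is the
#' sum of the 365 day means, so cumulative = 365 x mean exactly.
#'
#' @param clim A [build_climatology()] result.
#' @return A one-row tibble with `mean`, `sd`, `cumulative` (kJ m-2).
#' @export
annual_stats <- function(clim) {
  stopifnot("mean_dose" %in% names(clim))
  m <- mean(clim$mean_dose)
  tibble::tibble(mean = m, sd = stats::sd(clim$mean_dose),
                 cumulative = sum(clim$mean_dose))
}

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Day-weighted annual mean from monthly means
#'
#' Inverts the monthly summary back to an annual mean using non-leap month
#' lengths: sum(month_mean x days_in_month) / 365. Applied to a published
#' monthly table this reproduces the table's own annual column.
#'
#' @param monthly A data frame with `month` (1..12) and `mean` columns, or
#'   a numeric vector of 12 monthly means in calendar order.
#' @return Annual mean dose (kJ m-2).
#' @examples
#' annual_mean_from_monthly(rep(2, 12)) # 2
#' @export
annual_mean_from_monthly <- function(monthly) {
  if (is.numeric(monthly)) {
    stopifnot(length(monthly) == 12L)
    means <- monthly
  } else {
    stopifnot(all(c("month", "mean") %in% names(monthly)),
              nrow(monthly) == 12L)
    means <- monthly$mean[order(monthly$month)]
  }
  sum(means * DAYS_IN_MONTH) / 365
}

#' Peak-to-trough fold ratio of monthly means
#'
#' Ratio of the highest to the lowest monthly mean dose. A zero trough is
#' reported as `Inf` with a warning.
#'
#' @inheritParams annual_mean_from_monthly
#' @return A list with `fold`, `peak_month`, `trough_month`.
#' @export
peak_trough_ratio <- function(monthly) {
  if (is.numeric(monthly)) {
    stopifnot(length(monthly) == 12L)
    means <- monthly
    months <- 1:12
  } else {
    means <- monthly$mean
    months <- monthly$month
  }
  hi <- which.max(means)
  lo <- which.min(means)
  if (means[lo] <= 0) {
    warning("trough monthly mean is zero; fold ratio is infinite",
            call. = FALSE)
    fold <- Inf
  } else {
    fold <- means[hi] / means[lo]
  }
  list(fold = fold, peak_month = months[hi], trough_month = months[lo])
}

#' Vitamin D winter duration
#'
#' The number of climatological days whose mean D-UVB dose falls below the
#' threshold under which cutaneous vitamin D synthesis is considered
#' negligible (default 1 kJ m-2). Strictly below: boundary days equal to
#' the threshold count as synthesis days.
#'
#' @param clim A [build_climatology()] result (needs `month`, `day`,
#'   `mean_dose`).
#' @param threshold Dose threshold in kJ m-2. Default 1.
#' @return A list with `duration_days`, `threshold` and `below_days`
#'   (tibble of month, day).
#' @export
vitamin_d_winter <- function(clim, threshold = 1.0) {
  stopifnot(all(c("month", "day", "mean_dose") %in% names(clim)))
  below <- clim$mean_dose < threshold
  list(
    duration_days = sum(below),
    threshold = threshold,
    below_days = tibble::as_tibble(clim[below, c("month", "day")])
  )
}

#' Packaged monthly D-UVB climatology table for 46 European capitals
#'
#' Mean diurnal D-UVB dose (kJ m-2) and SD, annually and by month, for 46
#' European capital cities over an 18-year satellite record, as published;
#' transcribed verbatim into `inst/extdata/table1_duvb.csv`. Rows are
#' sorted by increasing latitude.
#'
#' @return A tibble with `city` and, for the annual plus 12 monthly
#'   columns, `<period>_mean` and `<period>_sd`.
#' @examples
#' t1 <- load_capital_table()
#' subset(t1, city == "Athens")$july_mean
#' @export
load_capital_table <- function() {
  path <- system.file("extdata", "table1_duvb.csv", package = "duvbclim",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Monthly means for one city from the packaged capital table
#'
#' @param city City name as it appears in [load_capital_table()].
#' @param table Optionally a pre-loaded capital table.
#' @return A tibble with `month` (1..12) and `mean` (kJ m-2).
#' @export
capital_monthly_means <- function(city, table = load_capital_table()) {
  row <- table[table$city == city, ]
  if (nrow(row) != 1L) stop("unknown city: ", city, call. = FALSE)
  months <- c("january", "february", "march", "april", "may", "june",
              "july", "august", "september", "october", "november",
              "december")
  tibble::tibble(
    month = 1:12,
    mean = as.numeric(row[paste0(months, "_mean")])
  )
}
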