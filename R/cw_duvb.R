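# Cumulative weighted D-UVB (CW-D-UVB): a recency-weighted sum of the 135
# daily doses strictly preceding a date, proxying circulating vitamin D
# status. The weighting reflects that recent exposure contributes more to
# the current 25(OH)D level than past exposure; with 25(OH)D's one-to-two
# month half-life the score peaks 30-60 days after the dose peak and is
# much smoother than the raw daily series.

#' Recency weight scheme for CW-D-UVB
#'
#' Two parametric reconstructions of a recency-weighted window are
#' provided: a linear taper w(k) = (L - k)/L over lags k = 0..L-1 (the
#' default), and a truncated exponential w(k) = 0.5^(k/half_life) motivated
#' by the 25(OH)D elimination half-life. Both start at w(0) = 1, are
#' non-increasing, and are deliberately NOT normalised to sum 1, so the
#' score keeps kJ m-2 units at the hundreds scale.
#'
#' @param form "linear_taper" or "exponential".
#' @param window_days Window length L in days. Default 135.
#' @param half_life_days Half-life in days (exponential form only).
#'   Default 45.
#' @return A list of class `weight_scheme` with the `weights` vector
#'   (lag 0 first).
#' @examples
#' sum(make_weights()$weights) # 68 for the default linear taper
#' @export
make_weights <- function(form = c("linear_taper", "exponential"),
                         window_days = 135, half_life_days = 45) {
  form <- match.arg(form)
  if (!is.finite(window_days) || window_days < 1)
    stop("window_days must be >= 1", call. = FALSE)
  window_days <- as.integer(window_days)
  k <- seq_len(window_days) - 1
  w <- switch(form,
    linear_taper = (window_days - k) / window_days,
    exponential = {
      if (!is.finite(half_life_days) || half_life_days <= 0)
        stop("half_life_days must be > 0", call. = FALSE)
      0.5^(k / half_life_days)
    }
  )
  structure(list(form = form, window_days = window_days,
                 half_life_days = half_life_days, weights = w),
            class = "weight_scheme")
}

#' CW-D-UVB series from a daily dose series
#'
#' CW(t) = sum over k = 1..L of w(k - 1) * dose(t - k): the weighted sum of
#' the L doses strictly preceding t (day t itself excluded). Dates whose
#' lookback window is incomplete (start of record, or any missing dose in
#' the window) get NA. The series must be on a contiguous daily calendar;
#' impute blackout days first.
#'
#' @param series A [duvb_series()].
#' @param scheme A [make_weights()] scheme.
#' @return A tibble with `date` and `cw_dose` (kJ m-2, NA where not
#'   computable), carrying the location as attribute `location`.
#' @export
cw_series <- function(series, scheme = make_weights()) {
  stopifnot(inherits(series, "duvb_series"), inherits(scheme, "weight_scheme"))
  rec <- series$records
  if (nrow(rec) > 1 && !all(diff(rec$date) == 1))
    stop("series must be on a contiguous daily calendar", call. = FALSE)
  L <- scheme$window_days
  n <- nrow(rec)
  dose <- rec$dose
  cw <- rep(NA_real_, n)
  if (n > L) {
    # columns: lags 1..L of the dose vector; NA propagates naturally
    idx <- (L + 1):n
    lagged <- vapply(seq_len(L), function(k) dose[idx - k],
                     numeric(length(idx)))
    cw[idx] <- as.numeric(lagged %*% scheme$weights)
  }
  out <- tibble::tibble(date = rec$date, cw_dose = cw)
  attr(out, "location") <- series$location
  out
}

#' Calendar-month means of a CW-D-UVB series
#'
#' @param cw A [cw_series()] result (or any tibble with `date`,
#'   `cw_dose`); NA values are dropped.
#' @return A tibble with `month` (1..12) and `cw_mean` (kJ m-2).
#' @export
monthly_cw <- function(cw) {
  stopifnot(all(c("date", "cw_dose") %in% names(cw)))
  ok <- !is.na(cw$cw_dose)
  if (!any(ok)) stop("no computable CW values", call. = FALSE)
  dat <- tibble::tibble(month = as.integer(format(cw$date[ok], "%m")),
                        cw_dose = cw$cw_dose[ok])
  dplyr::summarise(dplyr::group_by(dat, .data$month),
                   cw_mean = mean(.data$cw_dose), .groups = "drop")
}
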