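# Linking monthly CW-D-UVB to published monthly 25(OH)D means.
#
# Studies reporting mean 25(OH)D by calendar month are matched to the
# monthly CW-D-UVB profile of the capital of the country they were run in.
# For each study and month the differences relative to March (typically
# the 25(OH)D nadir) are formed on both axes, which removes study-level
# baselines; the pooled delta pairs within a cohort class (A population-
# based, B disease, C laboratory) are fit by ordinary least squares.

#' Read study-level monthly 25(OH)D tables
#'
#' Headered CSV with columns `study_id`, `cohort_class` (A/B/C),
#' `city_rule` (a capital name or "average(city1,city2)"), `month` (1..12)
#' and `mean_25ohd_nmol_l` (> 0).
#'
#' @param path CSV path.
#' @return A tibble of study monthly records.
#' @export
read_study_table <- function(path) {
  dat <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_study_table(dat)
}

validate_study_table <- function(dat) {
  need <- c("study_id", "cohort_class", "city_rule", "month",
            "mean_25ohd_nmol_l")
  if (!all(need %in% names(dat)))
    stop("study table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(dat$cohort_class %in% c("A", "B", "C")))
    stop("cohort_class must be A, B or C", call. = FALSE)
  if (!all(dat$month %in% 1:12))
    stop("month must be in 1..12", call. = FALSE)
  if (any(dat$mean_25ohd_nmol_l <= 0))
    stop("mean_25ohd_nmol_l must be > 0", call. = FALSE)
  dup <- duplicated(dat[, c("study_id", "month")])
  if (any(dup))
    stop("duplicate month within study: ",
         paste(unique(dat$study_id[dup]), collapse = ", "), call. = FALSE)
  dat
}

#' Resolve a city rule against a CW-D-UVB library
#'
#' A rule is either a single city name or "average(city1,city2)", in which
#' case the two monthly profiles are averaged elementwise (used for
#' territories lying between two covered capitals).
#'
#' @param city_rule Rule string.
#' @param cw_library Named list mapping city to a tibble with `month`,
#'   `cw_mean`, or a data frame with columns `city`, `month`, `cw_mean`.
#' @return A tibble with `month` (1..12) and `cw_mean`.
#' @export
resolve_city_cw <- function(city_rule, cw_library) {
  if (is.data.frame(cw_library))
    cw_library <- split(cw_library[, c("month", "cw_mean")], cw_library$city)
  lookup <- function(city) {
    city <- trimws(city)
    if (!city %in% names(cw_library))
      stop("city not in CW library: ", city, call. = FALSE)
    prof <- tibble::as_tibble(cw_library[[city]])
    stopifnot(all(1:12 %in% prof$month))
    prof[order(prof$month), c("month", "cw_mean")]
  }
  m <- regmatches(city_rule,
                  regexec("^average\\(([^,]+),([^)]+)\\)$", city_rule))[[1]]
  if (length(m) == 3) {
    a <- lookup(m[2])
    b <- lookup(m[3])
    return(tibble::tibble(month = a$month,
                          cw_mean = (a$cw_mean + b$cw_mean) / 2))
  }
  lookup(city_rule)
}

#' Per-month deltas relative to March
#'
#' For one study, pairs (CW(m) - CW(3), x25(m) - x25(3)) for every reported
#' month m other than March. March itself is (0, 0) by construction and is
#' excluded from the fit set. Studies without a March record are rejected.
#'
#' @param study Tibble of one study's monthly records (columns `study_id`,
#'   `month`, `mean_25ohd_nmol_l`).
#' @param cw_monthly Tibble with `month` (1..12) and `cw_mean` for the
#'   study's location.
#' @return A tibble with `study_id`, `month`, `delta_cw`, `delta_25ohd`.
#' @export
deltas_vs_march <- function(study, cw_monthly) {
  stopifnot(all(c("study_id", "month", "mean_25ohd_nmol_l") %in% names(study)),
            all(1:12 %in% cw_monthly$month))
  if (!3 %in% study$month)
    stop("study ", study$study_id[1],
         " has no March record; cannot form deltas", call. = FALSE)
  cw <- cw_monthly$cw_mean[order(cw_monthly$month)]
  x25_march <- study$mean_25ohd_nmol_l[study$month == 3]
  keep <- study$month != 3
  tibble::tibble(
    study_id = study$study_id[keep],
    month = study$month[keep],
    delta_cw = cw[study$month[keep]] - cw[3],
    delta_25ohd = study$mean_25ohd_nmol_l[keep] - x25_march
  )
}

#' Build the pooled delta-pair set for a cohort class
#'
#' @param studies A study table (see [read_study_table()]).
#' @param cw_library A CW library (see [resolve_city_cw()]).
#' @param cohort_class "A", "B", "C" or "all".
#' @return A tibble of delta pairs pooled across the class's studies;
#'   studies without a March record are dropped with a warning.
#' @export
class_delta_pairs <- function(studies, cw_library, cohort_class = "A") {
  validate_study_table(studies)
  if (cohort_class != "all")
    studies <- studies[studies$cohort_class == cohort_class, ]
  if (!nrow(studies)) stop("no studies in class ", cohort_class, call. = FALSE)
  out <- lapply(split(studies, studies$study_id), function(st) {
    cw <- resolve_city_cw(st$city_rule[1], cw_library)
    tryCatch(deltas_vs_march(st, cw), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  dplyr::bind_rows(out)
}

#' Ordinary least-squares fit of delta-25(OH)D on delta-CW-D-UVB
#'
#' Pooled OLS with intercept across the delta pairs of one cohort class.
#' The slope is in nmol/L per kJ m-2 of CW-D-UVB; `slope_per_100` rescales
#' it to the per-100 kJ m-2 convention used when reporting seasonal
#' 25(OH)D amplitudes. p-value is the two-sided t-test on the slope with
#' n - 2 degrees of freedom (NA for a saturated two-point fit).
#'
#' @param pairs A tibble with `delta_cw` and `delta_25ohd`.
#' @param weights Optional non-negative case weights (e.g. study sample
#'   sizes); default unweighted.
#' @return A one-row tibble: `slope`, `slope_per_100`, `intercept`,
#'   `r_squared`, `p_value`, `n_points`.
#' @export
fit_class_regression <- function(pairs, weights = NULL) {
  stopifnot(all(c("delta_cw", "delta_25ohd") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 delta pairs", call. = FALSE)
  if (stats::var(pairs$delta_cw) == 0)
    stop("delta_cw is constant; slope is not identifiable", call. = FALSE)
  fit <- if (is.null(weights)) {
    stats::lm(delta_25ohd ~ delta_cw, data = pairs)
  } else {
    stats::lm(delta_25ohd ~ delta_cw, data = pairs, weights = weights)
  }
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  p <- if (n > 2) unname(sm$coefficients["delta_cw", "Pr(>|t|)"]) else NA_real_
  tibble::tibble(
    slope = slope,
    slope_per_100 = 100 * slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = p,
    n_points = n
  )
}
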