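Package: duvbclim
Title: Vitamin-D-Effective UVB Climatology and Cumulative Weighted Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising ambient UVB radiation relevant for
    cutaneous vitamin D synthesis (D-UVB). Provides a clear-sky spectral
    simulator of daily vitamin-D-weighted UVB dose driven by solar geometry
    and a simplified ozone/Rayleigh atmosphere, readers for daily dose
    series with blackout-day imputation and a high-latitude winter cloud
    adjustment, day-of-year climatologies with monthly and annual summary
    statistics, the "vitamin D winter" duration statistic, the cumulative
    weighted D-UVB (CW-D-UVB) exposure score over a 135-day recency-weighted
    window, and a delta-versus-March regression linking monthly CW-D-UVB to
    published monthly 25-hydroxyvitamin D means. Includes a synthetic-data
    generator producing multi-year daily series and matched study tables
    with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
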