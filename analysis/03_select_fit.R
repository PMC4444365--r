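#!/usr/bin/env Rscript
# Stage 3: fit the rate-of-change model R_t ~ MFT_{t-1} + nLST + NAOi +
# fruit by GLS, selecting the ARMA error order and variance structure by
# ML/BIC with a parsimony tie-break, then refit the winner by REML for the
# reported coefficients.

library(oliverate)

series <- read_series("results/synthetic_series.csv")
rate <- rate_of_change(series)

sel <- select_model(rate, enumerate_candidates(),
                    control = gls_control(restarts = 1, reltol = 1e-8))
print(sel)
if (!sel$white_noise$pass)
  cat("Note: the white-noise check fails here because per-trap sampling\n",
      "error on the log abundance induces moving-average structure in the\n",
      "differenced series that no single low-order candidate fully absorbs;\n",
      "the SIMEX stage (04) addresses the measurement error directly.\n",
      sep = "")
cat("\nREML refit of the selected structure:\n")
print(sel$fit_reml)

write_selection_report(sel, "results/selection.csv")
write.csv(fit_to_table(sel$fit_reml), "results/fit_reml.csv",
          row.names = FALSE)
cat("written: results/selection.csv, results/fit_reml.csv\n")
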