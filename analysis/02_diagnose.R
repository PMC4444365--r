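#!/usr/bin/env Rscript
# Stage 2: temporal trend test and order diagnostics on the rate of
# population change. The PRCF's lag-1 entry (correlation of the detrended
# rate with the lagged log abundance) is the density-dependence signature;
# lags >= 2 diagnose delayed feedback.

library(oliverate)

series <- read_series("results/synthetic_series.csv")
dg <- diagnose_series(series)

cat(sprintf("Rates: %d usable month-to-month transitions\n", nrow(dg$rate)))
cat(sprintf("Trend in R_t: slope %.4f, adj R^2 %.3f, p = %.3f -> %s\n",
            dg$trend$slope, dg$trend$adj_r_squared, dg$trend$p_value,
            if (dg$trend$p_value < 0.05) "significant temporal trend"
            else "no temporal trend (stable rate of change)"))
b <- dg$prcf$bound[1]
cat(sprintf("PRCF lag 1 = %.3f (95%% bound +-%.3f) -> %s density dependence\n",
            dg$prcf$value[1], b,
            if (dg$prcf$value[1] < -b) "negative first-order" else "no clear"))
higher <- dg$prcf$lag[abs(dg$prcf$value) > b & dg$prcf$lag > 1]
cat("Higher-order PRCF signals at lags:",
    if (length(higher)) paste(higher, collapse = ", ") else "none", "\n")

write.csv(data.frame(slope = dg$trend$slope,
                     adj_r_squared = dg$trend$adj_r_squared,
                     f_statistic = dg$trend$f_statistic,
                     p_value = dg$trend$p_value),
          "results/trend.csv", row.names = FALSE)
write_correlogram(dg$acf, "results/acf.csv")
write_correlogram(dg$prcf, "results/prcf.csv")
cat("written: results/trend.csv, results/acf.csv, results/prcf.csv\n")
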