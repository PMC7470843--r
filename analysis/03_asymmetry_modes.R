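#!/usr/bin/env Rscript
# Outer-plaque asymmetry recovery and mode classification.
#
# Sweeps populations of short spindles generated at old:new outer-plaque
# fold-ratios 1, 2, 5 and 10 (outer-plaque-only query label), recovers the
# per-spindle asymmetry index from fitted amplitudes, classifies modes at
# the 8-fold / 1.3-fold boundaries, and writes both tables.

suppressPackageStartupMessages(library(spbquant))
dir.create("results", showWarnings = FALSE)

folds <- c(1, 2, 5, 10)
rows <- list(); mode_rows <- list()
for (k in seq_along(folds)) {
  f <- folds[k]
  out <- run_pipeline(run_config(
    n = 30, stage_mix = c(short_spindle_lt1 = 1),
    asymmetry = asymmetry_config(op_fold = f, ip_op_ratio = 0),
    seed = 300 + k))
  kept <- out$results[!out$results$excluded, ]
  expected <- (f - 1) / (f + 1)
  rows[[k]] <- tibble::tibble(
    fold = f, n = nrow(kept),
    expected_index = expected,
    median_index = median(kept$asymmetry_index, na.rm = TRUE),
    p25 = unname(summarize_distribution(kept$asymmetry_index)$centiles["p25"]),
    p75 = unname(summarize_distribution(kept$asymmetry_index)$centiles["p75"]))
  tb <- table(factor(kept$mode, levels = c("one_pole", "strongly_asymmetric",
                                           "asymmetric", "symmetric")))
  mode_rows[[k]] <- tibble::tibble(fold = f, mode = names(tb),
                                   count = as.integer(tb))
}
idx_tab <- do.call(rbind, rows)
write_result_table(idx_tab, "results/03_asymmetry_index.csv")
write_result_table(do.call(rbind, mode_rows), "results/03_mode_counts.csv")

cat("Asymmetry-index recovery across generated fold-ratios:\n")
print(as.data.frame(idx_tab), digits = 3)
cat("\nMode distribution per fold (counts):\n")
print(do.call(rbind, mode_rows), n = 16)
cat("\nFold 10 should sit near (10-1)/(10+1) = 0.818 and classify as\n",
    "strongly asymmetric; fold 1 near 0 and symmetric.\n")
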