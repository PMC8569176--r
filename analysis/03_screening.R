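#!/usr/bin/env Rscript
# Screens 220 pooled Sobol' parameter rows of the basic clv3-null model
# against the gradient selection criteria (L3:L1 in [3,6]; per-layer N-C
# in [0.5,2]; apex nuclear WUS above 1 in L1 and L2) and characterises
# the selected sets. About 220 simulations (~5 min).

library(wusgrad)
dir.create("results", showWarnings = FALSE)
seed <- 1L

graph <- build_sam_template()
design <- sobol_design(default_sobol_ranges(), n = 32L, seed = seed)
rows <- sobol_pooled_rows(design, 220L)

scr <- screen_parameter_sets(graph, rows)
print(scr)
utils::write.csv(scr$table, "results/screening_table.csv", row.names = FALSE)
utils::write.csv(scr$passing, "results/screening_passing.csv",
                 row.names = FALSE)

props <- selected_set_properties(scr$passing)
if (!props$insufficient) {
  cat("\nlog-log correlations among the passing sets:\n")
  print(props$correlations)
  cat("WUS decay lengths sqrt(D_w/d_wc):",
      paste(round(props$decay_length, 2), collapse = ", "), "\n")
  utils::write.csv(props$correlations, "results/screening_correlations.csv",
                   row.names = FALSE)
} else {
  cat("\nfewer than 3 passing sets at this seed; correlation report",
      "needs a pooled harvest across seeds (see the methods vignette)\n")
}
cat("\nThe passing count is of the same order as the handful the\n",
    "selection bands are designed to isolate; the exact count varies\n",
    "with the design seed.\n")
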