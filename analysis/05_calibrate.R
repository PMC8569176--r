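#!/usr/bin/env Rscript
# Reconstructs the shipped calibrated configuration from the screening
# output: anchors the CLV3 hat window and regulation EC50s to the
# realised tissue levels of a passing basic-model set, then accepts the
# first candidate satisfying the stability flip, the wild-type/clv3-null
# ratio targets and the repression-window condition.
#
# This is the slow, self-contained reproduction of the shipped
# inst/extdata/params_calibrated.json (tens of tissue simulations). The
# screening pool is harvested over several design seeds, as a single
# 220-row design may contain no set whose clv3-null ratio sits near 4.

library(wusgrad)
dir.create("results", showWarnings = FALSE)

graph <- build_sam_template()

# harvest passing sets over design seeds until a workable pool exists
pool <- NULL
for (seed in c(14L, 4L, 1L)) {
  design <- sobol_design(default_sobol_ranges(), n = 32L, seed = seed)
  scr <- screen_parameter_sets(graph, sobol_pooled_rows(design, 220L))
  cat("seed", seed, ":", scr$pass_count, "passing sets\n")
  if (scr$pass_count > 0) {
    scr$passing$seed <- seed
    pool <- rbind(pool, scr$passing)
  }
}
stopifnot(nrow(pool) > 0)
pooled <- list(passing = pool)
class(pooled) <- "screening_result"

cal <- calibrate_shipped_config(graph, pooled, base_params = sam_params())
info <- attr(cal, "calibration")
cat(sprintf("\ncalibrated: wild-type L3:L1 = %.2f, clv3-null = %.2f, hat peak = %.2f\n",
            info$wt_ratio, info$null_ratio, info$hat_peak))
write_params(cal, "results/params_recalibrated.json")
cat("wrote results/params_recalibrated.json\n")

shipped <- calibrated_params()
cat("\nshipped configuration reference values: wild-type", "\n")
wt <- run_to_steady(graph, shipped, variant("DUAL", "WT"))
print(wt)
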