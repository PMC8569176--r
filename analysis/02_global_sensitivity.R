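#!/usr/bin/env Rscript
# Global (Sobol' total-effect) sensitivity of the nuclear WUS level in
# L1-L3 with respect to the five screened rates, on the basic clv3-null
# model (no CLV3 feedback, no cytokinin, no self-stabilisation).
# About 224 tissue simulations; a few minutes on one CPU.

library(wusgrad)
dir.create("results", showWarnings = FALSE)
seed <- 1L

graph <- build_sam_template()
gs <- run_global_sensitivity(graph, basic_params(),
                             ranges = default_sobol_ranges(),
                             n = 32L, seed = seed)

tidy <- do.call(rbind, lapply(colnames(gs$total_effect), function(out) {
  data.frame(input = rownames(gs$total_effect), output = out,
             total_effect = gs$total_effect[, out],
             spearman = gs$spearman[, out], row.names = NULL)
}))
utils::write.csv(tidy, "results/global_sensitivity.csv", row.names = FALSE)
jsonlite::write_json(list(seed = seed, n = 32L,
                          ranges = as.data.frame(default_sobol_ranges())),
                     "results/global_sensitivity_provenance.json",
                     auto_unbox = TRUE, digits = NA)

cat("total-effect indices (rows: inputs; columns: nuclear WUS per layer):\n")
print(round(gs$total_effect, 3))
cat("\nrank-correlation signs:\n")
print(round(gs$spearman, 2))
cat("\nSynthesis correlates positively with nuclear WUS in every layer;\n",
    "both degradation rates correlate negatively. Diffusion is negative\n",
    "only inside the synthesis domain (L3) in this template geometry --\n",
    "see the methods vignette for the discussion.\n")
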