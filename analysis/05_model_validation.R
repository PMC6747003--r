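#!/usr/bin/env Rscript
# Stage 5 — validation experiments for the model-selection machinery.
#
# (a) 6x6 recovery matrix: 200 trios per generative pattern at the study
#     conditions (n = 62, standardized effects 1.0, residual SD 0.5),
#     classified by minimum BIC.
# (b) psQTL LRT calibration: 2,000 nulls where the genotype affects protein
#     only through mRNA; type-I error at 0.05 and KS distance to uniform.
# Writes results/recovery_matrix.tsv and results/lrt_calibration.tsv.

suppressPackageStartupMessages(library(cistrio))

set.seed(11)
reps <- 200L
confusion <- matrix(0L, 6, 6, dimnames = list(true = 1:6, selected = 1:6))
for (p in 1:6) {
  for (r in seq_len(reps)) {
    st <- simulate_trio(sim_params(n_individuals = 62, pattern_id = p))
    sel <- classify_trio(st$trio)$selected_pattern
    confusion[p, sel] <- confusion[p, sel] + 1L
  }
}
cat("Recovery matrix,", reps, "replicates per pattern:\n")
print(confusion)
cat("Diagonal recovery:",
    paste(sprintf("%.3f", diag(confusion) / reps), collapse = " "), "\n")
cat("(Patterns 3 and 6 are mutually confusable when the sampled mRNA-protein\n",
    "correlation is weak; see the methods vignette.)\n")

nsim <- 2000L
pvals <- vapply(seq_len(nsim), function(i) {
  st <- simulate_trio(sim_params(n_individuals = 62, pattern_id = 4,
                                 beta_NS = 0))
  lrt_psqtl(st$trio$N, st$trio$R, st$trio$S)$p_value
}, numeric(1))
t1 <- mean(pvals < 0.05)
ks <- unname(suppressWarnings(ks.test(pvals, "punif"))$statistic)
cat(sprintf("\npsQTL LRT under the mediated null (%d sims):\n", nsim))
cat(sprintf("  type-I error at 0.05: %.4f\n  KS distance to uniform: %.4f\n",
            t1, ks))

dir.create("results", showWarnings = FALSE)
write.table(as.data.frame.matrix(confusion), "results/recovery_matrix.tsv",
            sep = "\t", quote = FALSE)
write.table(data.frame(n_sims = nsim, type1_error_at_0.05 = t1,
                       ks_statistic = ks),
            "results/lrt_calibration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/recovery_matrix.tsv and results/lrt_calibration.tsv\n")
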