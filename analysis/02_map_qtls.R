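#!/usr/bin/env Rscript
# Stage 2 — preprocess expression and map cis QTLs.
#
# Reads the cohort from results/cohort/, normalizes each trait matrix
# (missingness filter, rank inverse-normal transform), then tests every
# gene x cis-candidate pair: mRNA ~ dosage (eQTL), protein ~ dosage (pQTL),
# and the protein-specific likelihood ratio test (psQTL). The
# Benjamini-Hochberg cutoff is applied at FDR 0.1 within each QTL type.
# Writes results/qtls.tsv and results/fdr_summary.tsv.

suppressPackageStartupMessages(library(cistrio))

geno <- read_genotypes("results/cohort/genotypes.tsv")
mrna <- normalize_expression(read_expression("results/cohort/mrna.tsv"))
protein <- normalize_expression(read_expression("results/cohort/protein.tsv"))
genes <- read_gene_bed("results/cohort/genes.bed")

res <- map_all_qtls(geno, mrna, protein, genes)

cat("Tested", nrow(res$records), "pair-type combinations across",
    length(unique(res$records$gene_id)), "genes\n")
cat("FDR 0.1 summary (per QTL type):\n")
print(res$fdr, row.names = FALSE)

write.table(res$records, "results/qtls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(res$fdr, "results/fdr_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/qtls.tsv and results/fdr_summary.tsv\n")
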