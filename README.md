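# cistrio

Cis-regulation analysis of SNP–mRNA–protein trios: map cis **eQTLs**,
**pQTLs** and **psQTLs** from genotype dosage and expression matrices,
classify each QTL–gene trio into one of **six regulatory patterns** by
Gaussian maximum likelihood and BIC, and quantify chromatin-state and
genomic-location enrichment of QTLs per pattern.

## The problem

A local genetic variant can raise a gene's protein level by raising its
mRNA — or it can act post-transcriptionally, leaving the transcript
unchanged. With genotype dosages *S*, mRNA levels *R* and protein levels
*N* measured on the same individuals, each candidate trio is scored under
six causal structures:

1. *S → R* (transcript only)
2. *S → N* (protein only)
3. *S → R*, *S → N* (both, independently)
4. *S → R → N* (protein change mediated by mRNA)
5. *S → N*, *R → N* (direct protein effect; mRNA–protein link not driven by this variant)
6. *S → R → N* plus *S → N* (combined)

Each structure is a factorization of the joint density built from Gaussian
components — class-mean densities *R* | *S*ⱼ ~ N(μ_RSⱼ, σ_R²),
*N* | *S*ⱼ ~ N(μ_NSⱼ, σ_N²), and bivariate-normal conditionals
*N* | *R* ~ N(μ_N + ρ(σ_N/σ_R)(R − μ_R), (1 − ρ²)σ_N²). Models are fit by
maximum likelihood (closed-form for the observed-genotype form), scored
with BIC = −2 log L + k log n at fixed parameter counts
k = (6, 6, 8, 8, 7, 10), and compared through weights
wᵢ = exp(−dBICᵢ) / Σ exp(−dBICₖ). psQTLs — protein effects that survive
conditioning on mRNA — come from the LRT of
`N ~ S + R` against `N ~ R`, statistic n·ln(RSS₀/RSS₁) ~ χ²₁.

A synthetic-cohort generator with known generative pattern per gene makes
every stage testable end to end: Hardy–Weinberg genotypes, pattern-built
traits, one causal variant per gene at the gene-body midpoint plus decoys
across the ±20-kb cis window.

## Worked example

Simulate one trio whose variant directly regulates protein abundance
(pattern 5) at the default study conditions — 62 individuals, standardized
effect 1.0, residual SD 0.5 — and classify it:

```r
library(cistrio)
st <- simulate_trio(sim_params(pattern_id = 5, seed = 42))
classify_trio(st$trio)
#> Regulatory pattern fit (form: observed , n = 62 )
#>  pattern     logL  k     BIC    dBIC    weight
#>        1 -203.527  6 431.816 115.950 4.399e-51
#>        2 -163.616  6 351.994  36.129 2.039e-16
#>        3 -162.268  8 357.553  41.688 7.857e-19
#>        4 -200.174  8 433.365 117.499 9.350e-52
#>        5 -143.488  7 315.866   0.000 9.999e-01
#>        6 -142.140 10 325.551   9.686 6.215e-05
#> Selected pattern: 5
```

Pattern 5 attains the smallest BIC and essentially all of the model
weight; pattern 6 fits marginally better in log-likelihood (it nests
pattern 5) but pays a three-parameter penalty. Running the whole pipeline
on a six-gene cohort (one gene per pattern):

```r
co  <- simulate_cohort(seed = 11)
res <- run_pipeline(co$genotypes, co$mrna, co$protein, co$genes,
                    config = pipeline_config(seed = 11))
res$fdr
#>   qtl_type fdr_level     p_cutoff n_tests n_discoveries
#> 1     eQTL       0.1 1.625088e-14      41             4
#> 2     pQTL       0.1 3.329017e-11      41             5
#> 3    psQTL       0.1 7.135694e-05      41             4
merge(res$patterns[, c("gene_id", "selected_pattern")],
      co$truth[, c("gene_id", "true_pattern")])
#>   gene_id selected_pattern true_pattern
#> 1 gene001                1            1
#> 2 gene002                2            2
#> 3 gene003                3            3
#> 4 gene004                4            4
#> 5 gene005                5            5
#> 6 gene006                6            6
```

Genes simulated under transcript-affecting patterns (1, 3, 4, 6) yield the
significant eQTLs; protein-affecting patterns (2, 3, 5, 6) yield the pQTLs
and psQTLs; and every gene's best-pQTL trio is classified back to its
generative pattern.

The `analysis/` directory holds the same workflow as numbered stand-alone
stages (simulate → map → classify → enrich → validate), each writing its
tables under `results/`.

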