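# MAF, cis candidate selection, OLS association, psQTL LRT, BH threshold,
# full mapping, and best-pQTL selection.

test_that("minor allele frequency folds to the minor side", {
  expect_equal(compute_maf(c(0, 0, 1, 1, 2)), 0.4)
  expect_equal(compute_maf(c(0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, 2, 2)), 0)
  expect_equal(compute_maf(c(2, 2, NA, 0)), 1 / 3)
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("cis window is gene body +/- 20 kb, 1-based inclusive, MAF strict", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 100000, end = 105000)
  variants <- data.frame(variant_id = c("in_edge", "out_edge", "body", "low_maf"),
                         chrom = "chr1",
                         pos = c(80000, 79999, 102000, 102500),
                         stringsAsFactors = FALSE)
  dos <- rbind(in_edge  = rep(c(0, 1, 2), 10),
               out_edge = rep(c(0, 1, 2), 10),
               body     = rep(c(0, 1, 2), 10),
               low_maf  = rep(c(0, 0, 0, 0, 1), 6))  # MAF exactly 0.10
  colnames(dos) <- paste0("s", 1:30)
  sel <- select_cis_candidates(gene, variants, dos)
  expect_setequal(sel$variant_id, c("in_edge", "body"))
  # MAF exactly at the threshold is excluded (strictly greater than)
  expect_false("low_maf" %in% sel$variant_id)
  expect_false("out_edge" %in% sel$variant_id)
})

test_that("OLS association equals the normal-equations oracle", {
  x <- c(0, 0, 1, 1, 2, 2)
  y <- 2 * x + c(0.1, -0.1, 0.05, -0.05, 0, 0)
  fit <- fit_linear_assoc(y, x)
  # hand-computed slope from the normal equations
  b_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$effect, b_oracle)
  # and against R's lm as an independent route
  lmf <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$effect, lmf[2, 1])
  expect_equal(fit$statistic, lmf[2, 3])
  expect_equal(fit$p_value, lmf[2, 4])
  expect_error(fit_linear_assoc(y, rep(1, 6)), "constant dosage")
  flat <- fit_linear_assoc(rep(2, 6), x)
  expect_equal(flat$effect, 0)
  expect_equal(flat$p_value, 1)
  expect_true(flat$degenerate)
})

test_that("association p-values are uniform under the permutation null", {
  set.seed(31)
  n <- 40
  x <- rep(0:2, length.out = n)
  p <- replicate(2000, fit_linear_assoc(rnorm(n), sample(x))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("t-test p equals the F-test of the same single-regressor model", {
  set.seed(32)
  for (i in 1:20) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- 0.3 * x + rnorm(30)
    fit <- fit_linear_assoc(y, x)
    ftab <- anova(lm(y ~ x))
    expect_equal(fit$p_value, ftab[["Pr(>F)"]][1])
    expect_equal(fit$statistic^2, ftab[["F value"]][1])
  }
})

test_that("psQTL LRT equals the residual-sum oracle and lmtest", {
  set.seed(33)
  n <- 8
  s <- c(0, 1, 2, 0, 1, 2, 0, 1)
  r <- rnorm(n)
  y <- 0.5 * s + 0.8 * r + rnorm(n, sd = 0.3)
  out <- lrt_psqtl(y, r, s)
  rss1 <- sum(resid(lm(y ~ s + r))^2)
  rss0 <- sum(resid(lm(y ~ r))^2)
  expect_equal(out$statistic, n * log(rss0 / rss1))
  expect_equal(out$p_value, pchisq(n * log(rss0 / rss1), 1, lower.tail = FALSE))
  lr <- lmtest::lrtest(lm(y ~ s + r), lm(y ~ r))
  expect_equal(out$statistic, lr$Chisq[2], tolerance = 1e-10)
  expect_equal(out$p_value, lr$`Pr(>Chisq)`[2], tolerance = 1e-10)
})

test_that("psQTL LRT handles nested equality and degenerate input", {
  r <- c(-1, 0, 1, 2, -0.5, 0.3)
  s <- c(0, 1, 2, 0, 1, 2)
  y <- 1.5 + 2 * r               # protein exactly linear in mRNA
  out <- lrt_psqtl(y, r, s)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(lrt_psqtl(rnorm(6), s * 2 - 1, s), "collinear")
  expect_error(lrt_psqtl(rnorm(6), rnorm(6), rep(1, 6)), "constant dosage")
})

test_that("LRT statistic is non-negative and detects protein-specific effects", {
  set.seed(34)
  stats_null <- numeric(200); stats_alt <- numeric(200)
  for (i in 1:200) {
    t4 <- simulate_trio(sim_params(pattern_id = 4, beta_NS = 0))$trio
    t5 <- simulate_trio(sim_params(pattern_id = 5, beta_NS = 0.8))$trio
    stats_null[i] <- lrt_psqtl(t4$N, t4$R, t4$S)$statistic
    stats_alt[i] <- lrt_psqtl(t5$N, t5$R, t5$S)$statistic
  }
  expect_true(all(stats_null >= 0) && all(stats_alt >= 0))
  rej_alt <- mean(pchisq(stats_alt, 1, lower.tail = FALSE) < 0.05)
  expect_gt(rej_alt, 0.5)  # well above the 0.05 null rate
})

test_that("BH threshold follows the step-up definition", {
  out <- bh_threshold(c(0.001, 0.02, 0.03, 0.5), fdr = 0.1)
  expect_equal(out$p_cutoff, 0.03)
  expect_equal(out$n_discoveries, 3)
  expect_equal(bh_threshold(rep(1, 5), 0.1)$n_discoveries, 0)
  expect_equal(bh_threshold(0.05, 0.1)$n_discoveries, 1)  # 0.05 <= 0.1, m = 1
  expect_equal(bh_threshold(0.2, 0.1)$n_discoveries, 0)
  expect_error(bh_threshold(numeric(0)), "no p-values")
  expect_error(bh_threshold(c(0.2, 1.4)), "0, 1")
})

test_that("BH discoveries agree with p.adjust on random vectors", {
  set.seed(35)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    out <- bh_threshold(p, fdr = 0.1)
    expect_equal(out$n_discoveries, sum(p.adjust(p, "BH") <= 0.1))
  }
})

test_that("mapping flags the generatively associated QTL types", {
  co <- simulate_cohort(seed = 11)
  res <- map_all_qtls(co$genotypes,
                      normalize_expression(co$mrna),
                      normalize_expression(co$protein), co$genes)
  rec <- merge(res$records, co$truth[, c("gene_id", "true_pattern")])
  causal <- rec[rec$variant_id == paste0(rec$gene_id, "_causal"), ]
  sig <- function(p, type)
    causal$significant[causal$true_pattern == p & causal$qtl_type == type]
  for (p in c(1, 3, 4, 6)) expect_true(sig(p, "eQTL"), label = paste("eQTL pattern", p))
  for (p in c(2, 3, 5, 6)) expect_true(sig(p, "pQTL"), label = paste("pQTL pattern", p))
  # determinism
  res2 <- map_all_qtls(co$genotypes,
                       normalize_expression(co$mrna),
                       normalize_expression(co$protein), co$genes)
  expect_identical(res, res2)
})

test_that("null cohorts stay near the nominal discovery rate", {
  co <- simulate_cohort(genes_per_pattern = c(200L, 0L, 0L, 0L, 0L, 0L),
                        beta_RS = 0, decoys_per_gene = 0L, seed = 17)
  res <- map_all_qtls(co$genotypes, normalize_expression(co$mrna),
                      normalize_expression(co$protein), co$genes)
  # all tests are truly null; BH keeps the false discovery proportion low
  prop <- mean(res$records$significant)
  expect_lte(prop, 0.12)
})

test_that("best pQTL per gene takes the smallest p regardless of significance", {
  rec <- data.frame(
    variant_id = c("v1", "v2", "v3", "w1", "x1", "x2"),
    gene_id = c("gA", "gA", "gA", "gB", "gC", "gC"),
    qtl_type = "pQTL",
    p_value = c(0.2, 0.04, 0.9, 0.5, 0.1, 0.1),
    pos = c(10, 20, 30, 5, 40, 25),
    dist_mid = c(15, 5, 5, 0, 10, 2),
    significant = FALSE, stringsAsFactors = FALSE)
  best <- best_pqtl_per_gene(rec)
  expect_equal(best$variant_id[best$gene_id == "gA"], "v2")  # 0.04, not significant
  expect_equal(best$variant_id[best$gene_id == "gB"], "w1")  # single candidate
  expect_equal(best$variant_id[best$gene_id == "gC"], "x2")  # tie -> nearer midpoint
  expect_error(best_pqtl_per_gene(rec[rec$qtl_type == "eQTL", ]), "no pQTL")
})
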