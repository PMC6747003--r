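# Cis QTL mapping: eQTL/pQTL single-regressor OLS, protein-specific QTL
# likelihood ratio test, Benjamini-Hochberg FDR cutoffs, and the
# best-pQTL-per-gene selection used for the first-round pattern analysis.

#' Minor allele frequency from dosages
#'
#' Alt-allele frequency `f = sum(dosages) / (2 m)` over the `m` non-missing
#' entries, folded to the minor side: `min(f, 1 - f)`.
#'
#' @param dosages Vector of 0/1/2 dosages, missing allowed.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  m <- sum(ok)
  if (m == 0L) stop("all dosages missing")
  f <- sum(dosages[ok]) / (2 * m)
  min(f, 1 - f)
}

#' Select cis candidate variants for a gene
#'
#' Returns the variants on the gene's chromosome whose position falls in the
#' window `[start - window_bp, end + window_bp]` (1-based inclusive, anchored
#' on the gene body) and whose minor allele frequency strictly exceeds
#' `maf_min`.
#'
#' @param gene One-row data frame or list with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param variants Data frame with `variant_id`, `chrom`, `pos`.
#' @param dosages Matrix of dosages (rownames = variant ids) used for the
#'   MAF filter.
#' @param window_bp Window half-width in bp.
#' @param maf_min MAF threshold (strict inequality).
#' @return Subset of `variants` with an added `maf` column (possibly empty).
#' @export
select_cis_candidates <- function(gene, variants, dosages,
                                  window_bp = 20000L, maf_min = 0.10) {
  lo <- gene$start - window_bp
  hi <- gene$end + window_bp
  hit <- variants$chrom == gene$chrom & variants$pos >= lo & variants$pos <= hi
  out <- variants[hit, , drop = FALSE]
  if (nrow(out) == 0L) { out$maf <- numeric(0); return(out) }
  out$maf <- apply(dosages[out$variant_id, , drop = FALSE], 1L, compute_maf)
  out[out$maf > maf_min, , drop = FALSE]
}

#' Single-variant association by ordinary least squares
#'
#' Regresses a trait on the dosage with an intercept; the two-sided p-value
#' comes from the t distribution with `n - 2` degrees of freedom. A constant
#' trait is reported as effect 0 with p = 1 (flagged degenerate) so that
#' FDR input lengths stay aligned.
#'
#' @param trait Numeric trait vector.
#' @param dosages Dosage vector (same length; pairwise complete cases used).
#' @return List: `effect`, `se`, `statistic`, `p_value`, `n_used`,
#'   `degenerate`.
#' @export
fit_linear_assoc <- function(trait, dosages) {
  ok <- !(is.na(trait) | is.na(dosages))
  y <- trait[ok]; x <- dosages[ok]
  n <- length(y)
  if (n < 3L) stop("fewer than 3 complete cases")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant dosage vector (degenerate input)")
  syy <- sum((y - mean(y))^2)
  if (syy == 0)
    return(list(effect = 0, se = NA_real_, statistic = 0, p_value = 1,
                n_used = n, degenerate = TRUE))
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- syy - b^2 * sxx
  se <- sqrt(max(rss, 0) / ((n - 2) * sxx))
  t <- if (se == 0) sign(b) * Inf else b / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(effect = b, se = se, statistic = t, p_value = p, n_used = n,
       degenerate = FALSE)
}

#' Protein-specific QTL likelihood ratio test
#'
#' Compares the Gaussian linear models
#' `N = b0 + b1 S + b2 R + e` (full) and `N = b0 + b2 R + e` (reduced);
#' the statistic is `2 (logL_full - logL_reduced) = n ln(RSS_reduced /
#' RSS_full)` with p from the chi-square distribution with 1 df. A protein
#' exactly linear in the mRNA gives statistic 0, p = 1.
#'
#' @param protein,mrna,dosages Aligned vectors (complete cases used).
#' @return List: `statistic`, `p_value`, `effect` (genotype coefficient in
#'   the full model), `n_used`.
#' @export
lrt_psqtl <- function(protein, mrna, dosages) {
  ok <- !(is.na(protein) | is.na(mrna) | is.na(dosages))
  y <- protein[ok]; r <- mrna[ok]; s <- dosages[ok]
  n <- length(y)
  if (n < 4L) stop("fewer than 4 complete cases")
  if (sum((s - mean(s))^2) == 0) stop("constant dosage vector (degenerate input)")
  if (sum((r - mean(r))^2) > 0 && abs(stats::cor(s, r)) >= 1 - 1e-12)
    stop("genotype and mRNA collinear (degenerate input)")
  full <- stats::lm.fit(cbind(1, s, r), y)
  red <- stats::lm.fit(cbind(1, r), y)
  rss1 <- sum(full$residuals^2)
  rss0 <- sum(red$residuals^2)
  if (rss0 <= 1e-12 * max(1, sum(y^2)))
    return(list(statistic = 0, p_value = 1,
                effect = unname(full$coefficients[2]), n_used = n))
  stat <- max(n * log(rss0 / rss1), 0)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       effect = unname(full$coefficients[2]), n_used = n)
}

#' Benjamini-Hochberg step-up p-value cutoff
#'
#' The cutoff is the largest order statistic `p_(i)` with
#' `p_(i) <= i * fdr / m`; discoveries are all p-values at or below it.
#' When no order statistic qualifies the cutoff is 0 with zero discoveries.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param fdr Target false discovery rate.
#' @return `fdr_result` list: `fdr_level`, `p_cutoff`, `n_discoveries`,
#'   `n_tests`, `method`.
#' @export
bh_threshold <- function(p_values, fdr = 0.1) {
  if (length(p_values) == 0L) stop("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * fdr / m)
  cutoff <- if (length(ok)) ps[max(ok)] else 0
  n_disc <- if (length(ok)) sum(p_values <= cutoff) else 0L
  structure(list(fdr_level = fdr, p_cutoff = cutoff,
                 n_discoveries = n_disc,
                 n_tests = m, method = "BH"),
            class = "fdr_result")
}

#' Map all cis eQTLs, pQTLs and psQTLs
#'
#' For every gene and every cis candidate variant, tests mRNA ~ dosage
#' (eQTL), protein ~ dosage (pQTL), and the protein-specific LRT (psQTL).
#' The Benjamini-Hochberg cutoff is computed separately within each QTL type
#' across all tested pairs; records at or below their type's cutoff are
#' flagged significant. Pairs with fewer complete cases than `min_complete`
#' or with degenerate dosages are skipped for that test.
#'
#' @param genotypes List with `variants` data frame (`variant_id`, `chrom`,
#'   `pos`) and `dosages` matrix (variants x samples).
#' @param mrna,protein Gene x sample matrices (already preprocessed).
#' @param genes Data frame of gene intervals (`gene_id`, `chrom`, `start`,
#'   `end`), 1-based inclusive.
#' @param window_bp,maf_min,fdr,min_complete Mapping settings.
#' @return List: `records` (one row per tested pair per type: `variant_id`,
#'   `gene_id`, `qtl_type`, `effect`, `statistic`, `p_value`, `n_used`,
#'   `pos`, `dist_mid`, `significant`), `fdr` (per-type summary data frame).
#' @export
map_all_qtls <- function(genotypes, mrna, protein, genes,
                         window_bp = 20000L, maf_min = 0.10, fdr = 0.1,
                         min_complete = 10L) {
  samples <- Reduce(intersect, list(colnames(genotypes$dosages),
                                    colnames(mrna), colnames(protein)))
  if (length(samples) == 0L) stop("no shared samples across input matrices")
  dos <- genotypes$dosages[, samples, drop = FALSE]
  mr <- mrna[, samples, drop = FALSE]
  pr <- protein[, samples, drop = FALSE]
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    if (!(gid %in% rownames(mr)) || !(gid %in% rownames(pr))) next
    cand <- select_cis_candidates(genes[g, ], genotypes$variants, dos,
                                  window_bp = window_bp, maf_min = maf_min)
    if (nrow(cand) == 0L) next
    gmid <- (genes$start[g] + genes$end[g]) / 2
    R <- mr[gid, ]; N <- pr[gid, ]
    for (v in seq_len(nrow(cand))) {
      vid <- cand$variant_id[v]
      S <- dos[vid, ]
      base <- data.frame(variant_id = vid, gene_id = gid,
                         pos = cand$pos[v],
                         dist_mid = abs(cand$pos[v] - gmid),
                         stringsAsFactors = FALSE)
      add <- function(type, fit) {
        cbind(base, data.frame(qtl_type = type, effect = fit$effect,
                               statistic = fit$statistic,
                               p_value = fit$p_value, n_used = fit$n_used,
                               stringsAsFactors = FALSE))
      }
      ne <- sum(!(is.na(R) | is.na(S)))
      np <- sum(!(is.na(N) | is.na(S)))
      nps <- sum(!(is.na(N) | is.na(R) | is.na(S)))
      if (ne >= min_complete) {
        fe <- tryCatch(fit_linear_assoc(R, S), error = function(e) NULL)
        if (!is.null(fe)) rows[[length(rows) + 1L]] <- add("eQTL", fe)
      }
      if (np >= min_complete) {
        fp <- tryCatch(fit_linear_assoc(N, S), error = function(e) NULL)
        if (!is.null(fp)) rows[[length(rows) + 1L]] <- add("pQTL", fp)
      }
      if (nps >= min_complete) {
        fs <- tryCatch(lrt_psqtl(N, R, S), error = function(e) NULL)
        if (!is.null(fs)) rows[[length(rows) + 1L]] <- add("psQTL", fs)
      }
    }
  }
  if (length(rows) == 0L) stop("no testable gene-variant pairs")
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  records$significant <- FALSE
  fdr_rows <- list()
  for (type in c("eQTL", "pQTL", "psQTL")) {
    idx <- records$qtl_type == type
    if (!any(idx)) next
    fr <- bh_threshold(records$p_value[idx], fdr = fdr)
    records$significant[idx] <- records$p_value[idx] <= fr$p_cutoff &
      fr$n_discoveries > 0
    fdr_rows[[type]] <- data.frame(qtl_type = type, fdr_level = fr$fdr_level,
                                   p_cutoff = fr$p_cutoff,
                                   n_tests = fr$n_tests,
                                   n_discoveries = fr$n_discoveries,
                                   stringsAsFactors = FALSE)
  }
  list(records = records, fdr = do.call(rbind, c(fdr_rows, make.row.names = FALSE)))
}

#' Best pQTL per gene (first-round selection)
#'
#' For each gene, keeps the single pQTL with the smallest p-value regardless
#' of significance. Exact p ties are broken toward the variant nearest the
#' gene-body midpoint, then the smallest coordinate.
#'
#' @param records QTL record data frame from [map_all_qtls()].
#' @return Data frame with one pQTL row per gene that had any tested
#'   candidate.
#' @export
best_pqtl_per_gene <- function(records) {
  pq <- records[records$qtl_type == "pQTL", , drop = FALSE]
  if (nrow(pq) == 0L) stop("no pQTL records present")
  ord <- order(pq$gene_id, pq$p_value, pq$dist_mid, pq$pos)
  pq <- pq[ord, , drop = FALSE]
  out <- pq[!duplicated(pq$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
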