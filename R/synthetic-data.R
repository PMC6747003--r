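# Synthetic genotype/mRNA/protein cohorts with known generative regulatory
# pattern per gene, so every downstream stage can be validated against truth.

.MAF_MIN <- 1e-6

#' Simulation parameters for one QTL-gene trio
#'
#' Effect sizes are specified on the standardized-trait scale: the dosage is
#' centered and scaled by its Hardy-Weinberg population moments
#' (mean `2 maf`, variance `2 maf (1 - maf)`) before effects are applied, so
#' a `beta` of 1 moves the trait by one unit per population SD of dosage
#' regardless of allele frequency. Defaults (n = 62, MAF 0.3, effects 1.0,
#' residual SDs 0.5) are the study conditions used throughout the package's
#' validation experiments.
#'
#' @param n_individuals Cohort size.
#' @param maf Alt-allele frequency in `(0, 0.5]` (practical lower bound 1e-6).
#' @param pattern_id Generative pattern, integer 1-6.
#' @param beta_RS Effect of genotype on mRNA (patterns 1, 3, 4, 6).
#' @param beta_NS Direct effect of genotype on protein (patterns 2, 3, 5, 6).
#' @param beta_NR Effect of mRNA on protein (patterns 4, 5, 6).
#' @param sigma_R,sigma_N Residual standard deviations (> 0).
#' @param seed Optional integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_individuals = 62L, maf = 0.3, pattern_id = 4L,
                       beta_RS = 1, beta_NS = 1, beta_NR = 1,
                       sigma_R = 0.5, sigma_N = 0.5, seed = NULL) {
  if (!pattern_id %in% 1:6) stop("pattern_id must be in 1..6")
  if (maf < .MAF_MIN || maf > 0.5)
    stop("maf must lie in (0, 0.5] (lower bound 1e-6)")
  if (sigma_R <= 0 || sigma_N <= 0) stop("residual SDs must be > 0")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  structure(list(n_individuals = as.integer(n_individuals), maf = maf,
                 pattern_id = as.integer(pattern_id),
                 beta_RS = beta_RS, beta_NS = beta_NS, beta_NR = beta_NR,
                 sigma_R = sigma_R, sigma_N = sigma_N, seed = seed),
            class = "sim_params")
}

#' Simulate biallelic genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each individual's alt-allele dosage is drawn as Binomial(2, maf), giving
#' genotype class frequencies `(1-maf)^2 : 2 maf (1-maf) : maf^2`.
#'
#' @param n Number of individuals.
#' @param maf Alt-allele frequency in `(0, 0.5]`; frequencies below 1e-6 are
#'   rejected as indistinguishable from monomorphic.
#' @param seed Optional integer seed (deterministic output given a seed).
#' @return Integer vector of dosages in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.numeric(maf) || maf < .MAF_MIN || maf > 0.5)
    stop("maf must lie in (0, 0.5] (lower bound 1e-6)")
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, maf)
}

# dosage standardized by population Hardy-Weinberg moments
.std_dosage <- function(S, maf) (S - 2 * maf) / sqrt(2 * maf * (1 - maf))

#' Simulate one trio under a known generative regulatory pattern
#'
#' Draws genotypes under Hardy-Weinberg and builds mRNA (R) and protein (N)
#' from the standardized dosage s by the pattern's structural equations:
#' \itemize{
#'   \item 1: `R = bRS*s + eR`, `N = eN`
#'   \item 2: `R = eR`, `N = bNS*s + eN`
#'   \item 3: `R = bRS*s + eR`, `N = bNS*s + eN` (independent errors)
#'   \item 4: `R = bRS*s + eR`, `N = bNR*R + eN`
#'   \item 5: `R = eR`, `N = bNS*s + bNR*R + eN`
#'   \item 6: `R = bRS*s + eR`, `N = bNS*s + bNR*R + eN`
#' }
#' with independent Gaussian errors `eR ~ N(0, sigma_R^2)`,
#' `eN ~ N(0, sigma_N^2)`. If the genotype draw is monomorphic it is redrawn
#' up to `max_retries` times, then an error is raised.
#'
#' @param params A [sim_params()] object.
#' @param normalize Apply [inverse_normal_transform()] to R and N.
#' @param max_retries Redraws allowed for monomorphic genotype vectors.
#' @return List with `trio` (a `trio_data`), and `truth` (pattern id and
#'   realized effect sizes).
#' @export
simulate_trio <- function(params, normalize = FALSE, max_retries = 100L) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_individuals
  S <- simulate_genotypes(n, params$maf)
  tries <- 0L
  while (length(unique(S)) < 2L) {
    tries <- tries + 1L
    if (tries > max_retries)
      stop("monomorphic genotypes after ", max_retries, " redraws; ",
           "increase n_individuals or maf")
    S <- simulate_genotypes(n, params$maf)
  }
  s <- .std_dosage(S, params$maf)
  eR <- stats::rnorm(n, 0, params$sigma_R)
  eN <- stats::rnorm(n, 0, params$sigma_N)
  p <- params$pattern_id
  R <- if (p %in% c(1L, 3L, 4L, 6L)) params$beta_RS * s + eR else eR
  N <- switch(p,
              eN,
              params$beta_NS * s + eN,
              params$beta_NS * s + eN,
              params$beta_NR * R + eN,
              params$beta_NS * s + params$beta_NR * R + eN,
              params$beta_NS * s + params$beta_NR * R + eN)
  if (normalize) {
    R <- inverse_normal_transform(R)
    N <- inverse_normal_transform(N)
  }
  truth <- list(true_pattern = p,
                beta_RS = if (p %in% c(1, 3, 4, 6)) params$beta_RS else 0,
                beta_NS = if (p %in% c(2, 3, 5, 6)) params$beta_NS else 0,
                beta_NR = if (p %in% c(4, 5, 6)) params$beta_NR else 0)
  list(trio = make_trio(S, R, N), truth = truth)
}

#' Simulate a full cohort: genotypes, mRNA, protein, gene map, truth table
#'
#' Lays genes out on one chromosome (100-kb spacing, 5-kb gene bodies) and,
#' for each gene, places one causal variant at the gene-body midpoint plus
#' decoy variants scattered uniformly across the cis window and slightly
#' beyond it (so window-boundary logic is exercised). Decoy dosages are
#' Hardy-Weinberg draws independent of the traits; trait vectors come from
#' [simulate_trio()] with the gene's assigned pattern.
#'
#' @param genes_per_pattern Integer vector of length 6: number of genes to
#'   simulate under each generative pattern.
#' @param n_individuals Cohort size.
#' @param maf Causal-variant alt-allele frequency.
#' @param decoys_per_gene Decoy variants per gene.
#' @param beta_RS,beta_NS,beta_NR,sigma_R,sigma_N Passed to [sim_params()].
#' @param missing_rate Fraction of expression cells set missing at random.
#' @param seed Integer seed; identical configuration + seed reproduces the
#'   cohort exactly.
#' @return List: `genotypes` (list with `variants` data frame and `dosages`
#'   matrix), `mrna` and `protein` (gene x sample matrices), `genes`
#'   (data frame: gene_id, chrom, start, end, strand; 1-based inclusive),
#'   `truth` (data frame: gene_id, causal_variant_id, true_pattern, betas).
#' @export
simulate_cohort <- function(genes_per_pattern = rep(1L, 6L),
                            n_individuals = 62L, maf = 0.3,
                            decoys_per_gene = 8L,
                            beta_RS = 1, beta_NS = 1, beta_NR = 1,
                            sigma_R = 0.5, sigma_N = 0.5,
                            missing_rate = 0, seed = 1L) {
  genes_per_pattern <- as.integer(genes_per_pattern)
  if (length(genes_per_pattern) != 6L || any(genes_per_pattern < 0L))
    stop("genes_per_pattern must be 6 non-negative counts")
  n_genes <- sum(genes_per_pattern)
  if (n_genes < 1L) stop("at least one gene must be requested")
  set.seed(seed)
  patterns <- rep(1:6, times = genes_per_pattern)
  samples <- sprintf("S%03d", seq_len(n_individuals))
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  gene_len <- 5000L; spacing <- 100000L
  starts <- 100000L + (seq_len(n_genes) - 1L) * spacing
  genes <- data.frame(gene_id = gene_ids, chrom = "chr1",
                      start = starts, end = starts + gene_len - 1L,
                      strand = "+", stringsAsFactors = FALSE)

  mrna <- matrix(NA_real_, n_genes, n_individuals,
                 dimnames = list(gene_ids, samples))
  protein <- mrna
  var_rows <- list(); dos_rows <- list()
  truth <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    p <- patterns[g]
    prm <- sim_params(n_individuals = n_individuals, maf = maf, pattern_id = p,
                      beta_RS = beta_RS, beta_NS = beta_NS, beta_NR = beta_NR,
                      sigma_R = sigma_R, sigma_N = sigma_N)
    st <- simulate_trio(prm)
    mid <- as.integer((genes$start[g] + genes$end[g]) %/% 2)
    causal_id <- sprintf("%s_causal", gene_ids[g])
    var_rows[[length(var_rows) + 1L]] <-
      data.frame(variant_id = causal_id, chrom = "chr1", pos = mid,
                 ref = "A", alt = "G", stringsAsFactors = FALSE)
    # trio dropped no cases here (no missingness yet); align by construction
    dos_rows[[length(dos_rows) + 1L]] <- st$trio$S
    # decoys across the window and 5 kb past it, avoiding the midpoint
    lo <- genes$start[g] - 25000L; hi <- genes$end[g] + 25000L
    dpos <- unique(round(stats::runif(decoys_per_gene, lo, hi)))
    dpos <- setdiff(as.integer(dpos), mid)
    for (k in seq_along(dpos)) {
      dmaf <- stats::runif(1, 0.15, 0.45)
      var_rows[[length(var_rows) + 1L]] <-
        data.frame(variant_id = sprintf("%s_decoy%02d", gene_ids[g], k),
                   chrom = "chr1", pos = dpos[k], ref = "C", alt = "T",
                   stringsAsFactors = FALSE)
      dos_rows[[length(dos_rows) + 1L]] <- simulate_genotypes(n_individuals, dmaf)
    }
    mrna[g, ] <- st$trio$R
    protein[g, ] <- st$trio$N
    truth[[g]] <- data.frame(gene_id = gene_ids[g], causal_variant_id = causal_id,
                             true_pattern = p,
                             beta_RS = st$truth$beta_RS, beta_NS = st$truth$beta_NS,
                             beta_NR = st$truth$beta_NR, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)
  dosages <- do.call(rbind, dos_rows)
  dimnames(dosages) <- list(variants$variant_id, samples)
  if (missing_rate > 0) {
    for (m in c("mrna", "protein")) {
      x <- get(m)
      x[stats::runif(length(x)) < missing_rate] <- NA_real_
      assign(m, x)
    }
  }
  # order variants by position for tidy output
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[ord, , drop = FALSE]
  rownames(variants) <- NULL
  list(genotypes = list(variants = variants, dosages = dosages),
       mrna = mrna, protein = protein, genes = genes,
       truth = do.call(rbind, truth))
}
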