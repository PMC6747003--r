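# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# one random trio with random pattern/effects, reproducible given seed
random_trio <- function(seed, n = NULL, pattern_id = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(30:120, 1)
  if (is.null(pattern_id)) pattern_id <- sample(1:6, 1)
  prm <- sim_params(n_individuals = n,
                    maf = runif(1, 0.15, 0.5),
                    pattern_id = pattern_id,
                    beta_RS = runif(1, 0.3, 1.5),
                    beta_NS = runif(1, 0.3, 1.5),
                    beta_NR = runif(1, 0.3, 1.5),
                    sigma_R = runif(1, 0.3, 1.2),
                    sigma_N = runif(1, 0.3, 1.2))
  simulate_trio(prm)$trio
}

# hand-built theta valid for every pattern (superset of all fields)
full_theta <- function() {
  list(mu_R_by_class = c(-0.5, 0.1, 0.8), sigma_R = 0.7,
       mu_N_by_class = c(-0.3, 0.2, 0.6), sigma_N = 0.9,
       rho = 0.4, mu_R = 0.05, mu_N = -0.1)
}

theta_for <- function(pattern_id) {
  fields <- list(
    c("mu_R_by_class", "sigma_R", "mu_N", "sigma_N"),
    c("mu_R", "sigma_R", "mu_N_by_class", "sigma_N"),
    c("mu_R_by_class", "sigma_R", "mu_N_by_class", "sigma_N"),
    c("mu_R_by_class", "sigma_R", "mu_N", "sigma_N", "rho", "mu_R"),
    c("mu_R", "sigma_R", "mu_N_by_class", "sigma_N", "rho"),
    c("mu_R_by_class", "mu_R", "sigma_R", "mu_N_by_class", "sigma_N", "rho"))
  full_theta()[fields[[pattern_id]]]
}

# tiny fixed trio for hand-checked likelihood arithmetic
toy_trio <- function() {
  make_trio(S = c(0L, 1L, 1L, 2L, 0L, 2L),
            R = c(-0.8, 0.1, 0.3, 1.1, -0.5, 0.9),
            N = c(-0.2, 0.0, 0.4, 0.7, -0.6, 1.0))
}

# exact upper-tail hypergeometric P(X >= k) by direct enumeration
hyper_tail_enum <- function(k, n_r, n, n_j) {
  kk <- k:min(n_r, n_j)
  sum(choose(n_r, kk) * choose(n - n_r, n_j - kk)) / choose(n, n_j)
}

# brute-force BH step-up: test every sorted p as a candidate cutoff
bh_brute <- function(p, fdr) {
  m <- length(p)
  ps <- sort(p)
  cutoff <- 0
  for (i in seq_len(m)) if (ps[i] <= i * fdr / m) cutoff <- max(cutoff, ps[i])
  list(p_cutoff = cutoff,
       n_discoveries = if (cutoff > 0 || any(ps <= seq_len(m) * fdr / m))
         sum(p <= cutoff) else 0L)
}
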