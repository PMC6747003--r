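# Six-model Gaussian likelihoods, closed-form and numerical MLEs, BIC
# scoring, model weights, and trio classification.

test_that("observed-form log-likelihood equals a per-term density oracle", {
  trio <- toy_trio()
  th <- theta_for(1)
  # independent per-term summation: class prior + R density + N density
  pri <- trio$class_priors
  oracle <- sum(log(pri[trio$S + 1]) +
                  dnorm(trio$R, th$mu_R_by_class[trio$S + 1], th$sigma_R, log = TRUE) +
                  dnorm(trio$N, th$mu_N, th$sigma_N, log = TRUE))
  expect_equal(pattern_loglik(1, trio, th), oracle, tolerance = 1e-10)
  # conditional protein density for the fully dependent model
  th6 <- theta_for(6)
  slope <- th6$rho * th6$sigma_N / th6$sigma_R
  csd <- th6$sigma_N * sqrt(1 - th6$rho^2)
  oracle6 <- sum(log(pri[trio$S + 1]) +
                   dnorm(trio$R, th6$mu_R_by_class[trio$S + 1], th6$sigma_R, log = TRUE) +
                   dnorm(trio$N, th6$mu_N_by_class[trio$S + 1] +
                           slope * (trio$R - th6$mu_R), csd, log = TRUE))
  expect_equal(pattern_loglik(6, trio, th6), oracle6, tolerance = 1e-10)
})

test_that("mixture-form log-likelihood marginalizes the genotype class", {
  trio <- toy_trio()
  th <- theta_for(3)
  pri <- trio$class_priors
  oracle <- sum(log(sapply(seq_len(trio$n), function(i)
    sum(sapply(1:3, function(j)
      pri[j] * dnorm(trio$R[i], th$mu_R_by_class[j], th$sigma_R) *
        dnorm(trio$N[i], th$mu_N_by_class[j], th$sigma_N))))))
  expect_equal(pattern_loglik(3, trio, th, form = "mixture"), oracle,
               tolerance = 1e-10)
})

test_that("rho = 0 collapses the dependent models onto the independent ones", {
  trio <- random_trio(41)
  th4 <- theta_for(4); th4$rho <- 0
  th1 <- theta_for(1)
  expect_equal(pattern_loglik(4, trio, th4), pattern_loglik(1, trio, th1))
  # equal class means for N collapse pattern 6 onto pattern 4
  th6 <- theta_for(6); th6$rho <- 0.4
  th6$mu_N_by_class <- rep(-0.1, 3)
  th4b <- theta_for(4); th4b$rho <- 0.4
  expect_equal(pattern_loglik(6, trio, th6), pattern_loglik(4, trio, th4b))
})

test_that("theta contract is enforced", {
  trio <- toy_trio()
  th <- theta_for(4); th$rho <- NULL
  expect_error(pattern_loglik(4, trio, th), "lacks field")
  th2 <- theta_for(1); th2$sigma_R <- -1
  expect_error(pattern_loglik(1, trio, th2), "> 0")
  expect_error(make_trio(rep(1L, 10), rnorm(10), rnorm(10)),
               "2 distinct genotype classes")
})

test_that("closed-form MLEs are the classical Gaussian estimates", {
  trio <- random_trio(42)
  cf1 <- closed_form_mle(1, trio)
  for (j in 0:2) if (any(trio$S == j))
    expect_equal(cf1$theta$mu_R_by_class[j + 1], mean(trio$R[trio$S == j]))
  ss <- sum((trio$R - cf1$theta$mu_R_by_class[trio$S + 1])^2)
  expect_equal(cf1$theta$sigma_R, sqrt(ss / trio$n))
  expect_equal(cf1$theta$mu_N, mean(trio$N))
  expect_equal(cf1$theta$sigma_N, sqrt(mean((trio$N - mean(trio$N))^2)))
})

test_that("conditional-model MLE reproduces least-squares fitted means", {
  trio <- random_trio(43)
  cf5 <- closed_form_mle(5, trio)
  th <- cf5$theta
  slope <- th$rho * th$sigma_N / th$sigma_R
  fitted_model <- th$mu_N_by_class[trio$S + 1] + slope * (trio$R - th$mu_R)
  ls <- lm(trio$N ~ 0 + factor(trio$S) + trio$R)
  expect_equal(fitted_model, unname(fitted(ls)), tolerance = 1e-6)
})

test_that("numerical MLE agrees with the closed form (optimizer-vs-oracle)", {
  for (seed in 1:5) {
    trio <- random_trio(seed)
    for (p in 1:6) {
      cf <- closed_form_mle(p, trio)
      nm <- fit_pattern_mle(p, trio)
      expect_lt(abs(nm$loglik - cf$loglik), 1e-4,
                label = sprintf("seed %d pattern %d dlogL", seed, p))
    }
  }
})

test_that("degenerate within-class-constant mRNA is flagged", {
  S <- c(0L, 0L, 1L, 1L, 2L, 2L)
  trio <- make_trio(S, R = c(1, 1, 2, 2, 3, 3), N = rnorm(6))
  cf <- closed_form_mle(1, trio)
  expect_true(cf$degenerate)
  expect_equal(cf$theta$sigma_R, 1e-6)
})

test_that("class-mean estimates approach the grand mean when no effect exists", {
  set.seed(44)
  st <- simulate_trio(sim_params(n_individuals = 5000, pattern_id = 2,
                                 beta_NS = 0))
  cf <- closed_form_mle(2, st$trio)
  expect_true(all(abs(cf$theta$mu_N_by_class - mean(st$trio$N)) < 0.1))
})

test_that("parameters are recovered on large simulated data", {
  set.seed(45)
  b_RS <- 1; b_NR <- 1; s_R <- 0.5; s_N <- 0.5; maf <- 0.3
  st <- simulate_trio(sim_params(n_individuals = 5000, pattern_id = 4,
                                 beta_RS = b_RS, beta_NR = b_NR,
                                 sigma_R = s_R, sigma_N = s_N, maf = maf))
  cf <- closed_form_mle(4, st$trio)
  # generative class means of R on the standardized-dosage scale
  sd_dos <- sqrt(2 * maf * (1 - maf))
  mu_gen <- b_RS * ((0:2 - 2 * maf) / sd_dos)
  expect_equal(cf$theta$mu_R_by_class, mu_gen, tolerance = 0.1)
  expect_equal(cf$theta$sigma_R, s_R, tolerance = 0.05)
  # implied regression slope of N on R equals b_NR
  expect_equal(cf$theta$rho * cf$theta$sigma_N / cf$theta$sigma_R, b_NR,
               tolerance = 0.05)
})

test_that("BIC arithmetic is exact", {
  expect_equal(bic_score(0, 0, 10), 0)
  expect_equal(bic_score(-100, 6, 62), 200 + 6 * log(62))
  expect_equal(200 + 6 * log(62), 224.7628, tolerance = 1e-4)
  expect_equal(bic_score(-50, 7, 62) - bic_score(-50, 6, 62), log(62))
})

test_that("BIC weights follow exp(-dBIC) with the printed exponent", {
  expect_equal(bic_weights(rep(5, 6)), rep(1 / 6, 6))
  w <- bic_weights(c(10, 12, 14, 100, 100, 100))
  d <- c(0, 2, 4, 90, 90, 90)
  expect_equal(w, exp(-d) / sum(exp(-d)))
  expect_equal(w[1:3], c(0.8668, 0.1173, 0.0159), tolerance = 1e-3)
  # conventional exponent available
  w2 <- bic_weights(c(10, 12, 14, 100, 100, 100), exponent = 0.5)
  expect_equal(w2, exp(-d / 2) / sum(exp(-d / 2)))
  expect_error(bic_weights(c(1, NA, 3, 4, 5, 6)), "finite")
})

test_that("weights sum to one, the best model dominates, and shifts cancel", {
  set.seed(46)
  for (i in 1:20) {
    b <- rnorm(6, 100, 20)
    w <- bic_weights(b)
    expect_lt(abs(sum(w) - 1), 1e-10)
    expect_equal(which.max(w), which.min(b))
    expect_gte(max(w), 1 / 6)
    expect_equal(w, bic_weights(b + 57.3), tolerance = 1e-12)
  }
})

test_that("strong-signal trios are classified to their generative pattern", {
  set.seed(47)
  t4 <- simulate_trio(sim_params(n_individuals = 500, pattern_id = 4))$trio
  expect_equal(classify_trio(t4)$selected_pattern, 4L)
  t2 <- simulate_trio(sim_params(n_individuals = 500, pattern_id = 2))$trio
  expect_equal(classify_trio(t2)$selected_pattern, 2L)
})

test_that("pattern 6 nests all other patterns at the observed-form MLE", {
  for (seed in 101:120) {
    trio <- random_trio(seed)
    ll <- vapply(1:6, function(p) closed_form_mle(p, trio)$loglik, numeric(1))
    expect_gte(ll[6], max(ll[1:5]) - 1e-6)
  }
})

test_that("observed-form selection is invariant to the class priors", {
  # priors multiply every model identically, so they cancel in dBIC
  trio <- random_trio(48)
  fit <- classify_trio(trio)
  trio2 <- trio
  trio2$class_priors <- c(1 / 3, 1 / 3, 1 / 3)
  fit2 <- classify_trio(trio2)
  expect_identical(fit$selected_pattern, fit2$selected_pattern)
  expect_equal(fit$dbic, fit2$dbic, tolerance = 1e-9)
  expect_equal(fit$weight, fit2$weight, tolerance = 1e-9)
})

test_that("mixture-form classification runs and prefers a dependent model", {
  set.seed(49)
  t4 <- simulate_trio(sim_params(n_individuals = 300, pattern_id = 4))$trio
  fit <- classify_trio(t4, form = "mixture")
  expect_lt(abs(sum(fit$weight) - 1), 1e-10)
  expect_true(fit$selected_pattern %in% c(4L, 6L))
  expect_error(classify_trio(t4, form = "mixture", method = "closed_form"),
               "observed-genotype")
})
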