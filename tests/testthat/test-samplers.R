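test_that("omega-site conditional equals the two-point enumeration oracle", {
  h <- assembly_hyper(alpha_p = 1.2, beta_p = 0.8, alpha_lambda0 = 1.5,
                      beta_lambda0 = 0.7, alpha_lambda1 = 0.6, beta_lambda1 = 1.3)
  set.seed(21)
  for (rep in 1:15) {
    inst <- rand_instance(3, 4, 2)
    k <- sample(4, 1); mu <- sample(2, 1)
    o1 <- inst$omega; o1[k, mu] <- 1L
    o0 <- inst$omega; o0[k, mu] <- 0L
    l1 <- marginal_log_likelihood(inst$t, o1, inst$s, h)
    l0 <- marginal_log_likelihood(inst$t, o0, inst$s, h)
    expect_equal(omega_conditional(inst$t, inst$omega, inst$s, h, k, mu),
                 1 / (1 + exp(l0 - l1)), tolerance = 1e-12)
  }
})

test_that("omega conditional for an empty assembly is the pure prior predictive", {
  h <- assembly_hyper(alpha_p = 2, beta_p = 3)
  # assembly 2 has no members: conditional depends only on the on/off counts
  t <- c(1L, 1L); omega <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3, 2)
  s <- matrix(rbinom(6, 1, .5), 2, 3)
  m1_other <- sum(omega[-2L, 2L])
  expected <- (m1_other + h$alpha_p) /
    (m1_other + h$alpha_p + (nrow(omega) - 1 - m1_other) + h$beta_p)
  expect_equal(omega_conditional(t, omega, s, h, k = 2, mu = 2), expected)
})

test_that("membership conditional equals the enumeration oracle and trivial cases", {
  h <- assembly_hyper()
  set.seed(22)
  for (rep in 1:15) {
    inst <- rand_instance(3, 4, 2)
    i <- sample(3, 1)
    ref <- vapply(1:2, function(mu) {
      tt <- inst$t; tt[i] <- mu
      marginal_log_likelihood(tt, inst$omega, inst$s, h)
    }, numeric(1))
    ref <- exp(ref - max(ref)); ref <- ref / sum(ref)
    expect_equal(membership_conditional(inst$t, inst$omega, inst$s, h, i), ref,
                 tolerance = 1e-12)
  }
  # identical omega columns and identical leave-one-out member activity: the
  # Beta-ratio cancels and the weights reduce to leave-one-out G + alpha_n
  om <- matrix(rbinom(8, 1, .5), 4, 2); om[, 2] <- om[, 1]
  s <- matrix(rbinom(12, 1, .5), 3, 4)
  s[3, ] <- s[2, ]                       # assemblies 1, 2 see the same evidence
  pr <- membership_conditional(c(1L, 1L, 2L), om, s, h, i = 1)
  expect_equal(pr, c(0.5, 0.5), tolerance = 1e-12)
  # single assembly: no choice
  expect_equal(membership_conditional(rep(1L, 3), om[, 1, drop = FALSE], s, h, 2), 1)
})

test_that("theta draws target the conjugate posterior", {
  h <- assembly_hyper()
  set.seed(23)
  inst <- rand_instance(4, 6, 2)
  st <- suff_stats(inst$t, inst$omega, inst$s, h)
  Tt <- neuroassembly:::stats_T(st)
  draws <- replicate(20000, sample_theta(inst$t, inst$omega, inst$s, h)$lambda1[1])
  expect_lt(abs(mean(draws) - Tt[1, 2, 2] / (Tt[1, 2, 2] + Tt[1, 2, 1])),
            3 * sd(draws) / sqrt(20000) + 1e-3)
})

test_that("fixed-A Gibbs targets the exact posterior on a tiny instance", {
  set.seed(24)
  h <- assembly_hyper()
  s <- matrix(rbinom(12, 1, .5), 3, 4)
  exact <- enum_posterior_fixedA(s, h, A = 2)
  tr <- gibbs_run(s, A = 2, hyper = h, n_iter = 20000, burn_in = 1000,
                  thin = 1, seed = 25, record_omega = FALSE, record_theta = FALSE)
  emp <- table(factor(apply(tr$t_samples, 1, canon_partition),
                      levels = names(exact))) / nrow(tr$t_samples)
  n_eff <- nrow(tr$t_samples) / 5        # conservative autocorrelation discount
  for (k in names(exact)) {
    se <- sqrt(exact[[k]] * (1 - exact[[k]]) / n_eff)
    expect_lt(abs(emp[[k]] - exact[[k]]), 4 * se)
  }
})

test_that("DP sampler targets the exact CRP posterior on a tiny instance", {
  set.seed(26)
  h <- assembly_hyper()
  s <- matrix(rbinom(12, 1, .5), 3, 4)
  exact <- enum_posterior_dp(s, h)
  tr <- dp_run(s, hyper = h, n_iter = 30000, burn_in = 2000, thin = 1,
               seed = 27, record_omega = FALSE, record_theta = FALSE)
  emp <- table(factor(apply(tr$t_samples, 1, canon_partition),
                      levels = names(exact))) / nrow(tr$t_samples)
  n_eff <- nrow(tr$t_samples) / 5
  for (k in names(exact)) {
    se <- sqrt(exact[[k]] * (1 - exact[[k]]) / n_eff)
    expect_lt(abs(emp[[k]] - exact[[k]]), 4 * se)
  }
})

test_that("DP sampler handles the all-zero matrix and deletes empty assemblies", {
  s <- matrix(0L, 6, 10)
  tr <- dp_run(s, n_iter = 200, seed = 28)
  expect_true(tr$A_final >= 1)
  expect_true(all(is.finite(tr$loglik)))
  expect_equal(length(tr$t_final), 6L)
  # no events: the asynchronous firing estimate collapses to zero, and the
  # synchronous one stays a valid probability dominated by its prior
  sm <- assembly_summary(tr)
  expect_true(all(sm$lambda0 < 0.25))
  expect_true(all(sm$lambda1 >= 0 & sm$lambda1 <= 1))
})

test_that("detectable-regime run recovers the planted partition exactly", {
  mod <- assembly_model(rep(1, 3), p = 0.15, lambda0 = 0.05, lambda1 = 0.7)
  sim <- simulate_assemblies(mod, N = 60, M = 400, seed = 29, equal_sizes = TRUE)
  tr <- dp_run(sim$s, n_iter = 300, seed = 30)
  expect_equal(tr$A_final, 3L)
  expect_equal(performance(tr$t_final, sim$t), 1)
  dg <- diagnostics(tr)
  expect_true(dg$converged)
  expect_equal(tail(tr$trans_rate, 1), 0)
})

test_that("diagnostics reports rates, A trajectory and convergence flags", {
  mod <- assembly_model(rep(1, 2), p = 0.2, lambda0 = 0.05, lambda1 = 0.8)
  sim <- simulate_assemblies(mod, 20, 100, seed = 31)
  tr <- gibbs_run(sim$s, A = 2, n_iter = 60, seed = 32)
  dg <- diagnostics(tr, rate_threshold = 2, window = 5)  # any rate counts
  expect_named(dg$sweeps, c("iteration", "loglik", "trans_rate", "A"))
  expect_true(all(tr$trans_rate >= 0 & tr$trans_rate <= 1))
  expect_true(dg$converged)
  dg2 <- diagnostics(tr, rate_threshold = -1, window = 5)  # unattainable
  expect_false(dg2$converged)
  # running maximum of the log marginal likelihood plateaus
  rmax <- cummax(tr$loglik)
  expect_lt(diff(range(tail(rmax, 10))), abs(0.01 * rmax[length(rmax)]) + 1)
})

test_that("non-detectable regime keeps a positive mean transition rate", {
  mod <- assembly_model(rep(1, 3), p = 0.15, lambda0 = 0.3, lambda1 = 0.3)
  sim <- simulate_assemblies(mod, 45, 300, seed = 33, equal_sizes = TRUE)
  tr <- dp_run(sim$s, n_iter = 300, seed = 34, record_omega = FALSE,
               record_theta = FALSE)
  expect_gt(mean(tr$trans_rate), 0.02)
  expect_lt(performance(tr$t_final, sim$t), 1)
})

test_that("posterior summaries, alignment and membership confidence behave", {
  mod <- assembly_model(rep(1, 3), p = 0.15, lambda0 = 0.05, lambda1 = 0.7)
  sim <- simulate_assemblies(mod, N = 45, M = 400, seed = 35, equal_sizes = TRUE)
  tr <- dp_run(sim$s, n_iter = 250, burn_in = 150, thin = 2, seed = 36)
  mp <- membership_posterior(tr)
  expect_equal(nrow(mp), 45L)
  expect_true(all(mp$confidence > 0.9))           # frozen detectable chain
  expect_equal(performance(mp$assembly, sim$t), 1)
  sm <- assembly_summary(tr)
  expect_equal(nrow(sm), 3L)
  expect_equal(sort(sm$G), c(15, 15, 15), tolerance = 0.05)
  expect_true(all(abs(sm$lambda1 - 0.7) < 0.15))
  expect_true(all(abs(sm$lambda0 - 0.05) < 0.05))
  opm <- omega_posterior_mean(tr)
  expect_equal(dim(opm), c(400L, 3L))
  expect_true(all(opm >= 0 & opm <= 1))
})
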