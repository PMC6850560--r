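test_that("simulated activity matches the mixture firing rate and degenerate limits", {
  mod <- assembly_model(rep(1, 5), p = 0.1, lambda0 = 0.08, lambda1 = 0.6)
  sim <- simulate_assemblies(mod, N = 500, M = 1000, seed = 1, equal_sizes = TRUE)
  expect_equal(dim(sim$s), c(500L, 1000L))
  expect_true(all(sim$s %in% 0:1))
  # per-neuron firing frequency clusters around p*lambda1 + (1-p)*lambda0 = 0.132
  target <- 0.1 * 0.6 + 0.9 * 0.08
  expect_lt(abs(mean(sim$s) - target), 3 * sqrt(target * (1 - target) / length(sim$s)) + 0.01)
  rates <- rowMeans(sim$s)
  expect_gt(mean(abs(rates - target) < 5 * sqrt(0.132 * 0.868 / 1000)), 0.95)

  z <- simulate_assemblies(assembly_model(1, p = 0.5, lambda0 = 0, lambda1 = 0),
                           N = 10, M = 20, seed = 2)
  expect_true(all(z$s == 0L))
  o <- simulate_assemblies(assembly_model(1, p = 1 - 1e-12, lambda0 = 0.3,
                                          lambda1 = 1), N = 10, M = 20, seed = 3)
  expect_true(all(o$omega == 1L))
  expect_true(all(o$s == 1L))
  expect_error(assembly_model(1, p = 1.2, lambda0 = .1, lambda1 = .5), "p")
})

test_that("simulation is reproducible given the seed", {
  mod <- assembly_model(rep(1, 3), p = 0.2, lambda0 = 0.05, lambda1 = 0.7)
  a <- simulate_assemblies(mod, 30, 40, seed = 9)
  b <- simulate_assemblies(mod, 30, 40, seed = 9)
  expect_identical(a$s, b$s); expect_identical(a$t, b$t); expect_identical(a$omega, b$omega)
})

test_that("joint log-likelihood: single-factor case, label symmetry, impossible events", {
  mod1 <- assembly_model(1, p = 0.1, lambda0 = 0.2, lambda1 = 0.6)
  val <- full_log_likelihood(1L, matrix(1L, 1, 1), matrix(1L, 1, 1), mod1)
  expect_equal(val, log(0.1 * 0.6))

  set.seed(4)
  inst <- rand_instance(4, 3, 2)
  mod <- assembly_model(c(.3, .7), p = c(.2, .5), lambda0 = c(.1, .2),
                        lambda1 = c(.8, .6))
  base <- full_log_likelihood(inst$t, inst$omega, inst$s, mod)
  # permute assembly labels jointly in (t, omega, params)
  perm <- c(2L, 1L)
  modp <- assembly_model(mod$n[perm], mod$p[perm], mod$lambda0[perm], mod$lambda1[perm])
  expect_equal(full_log_likelihood(perm[inst$t], inst$omega[, perm], inst$s, modp), base)

  mod0 <- assembly_model(1, p = .5, lambda0 = 1e-300, lambda1 = 0)
  expect_identical(full_log_likelihood(1L, matrix(1L, 1, 1), matrix(1L, 1, 1), mod0), -Inf)
})

test_that("joint likelihood normalizes to 1 over all (t, omega, s) configurations", {
  mod <- assembly_model(c(.3, .7), p = c(.2, .6), lambda0 = c(.1, .3),
                        lambda1 = c(.8, .5))
  N <- 2; M <- 2; A <- 2
  tot <- 0
  tgrid <- as.matrix(expand.grid(rep(list(1:A), N)))
  for (r in seq_len(nrow(tgrid))) {
    for (om in all_omegas(M, A)) {
      sgrid <- as.matrix(expand.grid(rep(list(0:1), N * M)))
      for (q in seq_len(nrow(sgrid))) {
        s <- matrix(as.integer(sgrid[q, ]), N, M)
        tot <- tot + exp(full_log_likelihood(tgrid[r, ], om, s, mod))
      }
    }
  }
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("marginal likelihood matches quadrature of the joint against the priors", {
  h <- assembly_hyper(alpha_p = 1.3, beta_p = 0.7, alpha_lambda0 = 2,
                      beta_lambda0 = 1.1, alpha_lambda1 = 0.9,
                      beta_lambda1 = 1.4, alpha_n = 1.5)
  set.seed(11)
  for (rep in 1:8) {
    N <- sample(2:4, 1); M <- sample(2:4, 1); A <- sample(1:2, 1)
    inst <- rand_instance(N, M, A)
    expect_equal(marginal_log_likelihood(inst$t, inst$omega, inst$s, h),
                 quad_marginal(inst$t, inst$omega, inst$s, h),
                 tolerance = 1e-8)
  }
})

test_that("marginal likelihood: Beta symmetry and label exchangeability", {
  h <- assembly_hyper()   # symmetric unit hyperparameters
  om <- matrix(1L, 1, 1)
  expect_equal(marginal_log_likelihood(1L, om, matrix(0L, 1, 1), h),
               marginal_log_likelihood(1L, om, matrix(1L, 1, 1), h))
  set.seed(12)
  inst <- rand_instance(4, 3, 2)
  perm <- c(2L, 1L)
  expect_equal(
    marginal_log_likelihood(perm[inst$t], inst$omega[, perm], inst$s, h),
    marginal_log_likelihood(inst$t, inst$omega, inst$s, h))
  expect_error(marginal_log_likelihood(inst$t, inst$omega, inst$s,
                                       assembly_hyper(alpha_p = -1)), "positive")
})

test_that("collapsed marginal equals the prior average of the joint likelihood", {
  h <- assembly_hyper()
  set.seed(13)
  inst <- rand_instance(3, 3, 2)
  n_mc <- 40000
  draws <- vapply(seq_len(n_mc), function(r) {
    g <- rgamma(2, 1)
    mod <- assembly_model(g / sum(g), p = rbeta(2, 1, 1),
                          lambda0 = rbeta(2, 1, 1), lambda1 = rbeta(2, 1, 1))
    exp(full_log_likelihood(inst$t, inst$omega, inst$s, mod))
  }, numeric(1))
  mc <- mean(draws); se <- sd(draws) / sqrt(n_mc)
  expect_lt(abs(mc - exp(marginal_log_likelihood(inst$t, inst$omega, inst$s, h))),
            3 * se)
})

test_that("incremental sufficient statistics equal batch recomputation exactly", {
  h <- assembly_hyper(alpha_p = 1.1, beta_p = 0.9)
  set.seed(14)
  N <- 8; M <- 10; A <- 3
  inst <- rand_instance(N, M, A)
  st <- suff_stats(inst$t, inst$omega, inst$s, h)
  expect_equal(sum(st$G), N)
  expect_equal(stats_H(st) + stats_Hbar(st),
               rep(M + h$alpha_p + h$beta_p, A))

  # involution: a move followed by its inverse restores the stats
  st1 <- update_stats(st, list(type = "membership", i = 1, to = (st$t[1] %% A) + 1L))
  st2 <- update_stats(st1, list(type = "membership", i = 1, to = st$t[1]))
  expect_identical(st2$counts, st$counts); expect_identical(st2$G, st$G)

  # 1000 random single-site moves stay bit-exact against recomputation
  for (mv in 1:1000) {
    if (runif(1) < 0.5) {
      st <- update_stats(st, list(type = "membership", i = sample(N, 1),
                                  to = sample(A, 1)))
    } else {
      st <- update_stats(st, list(type = "omega", k = sample(M, 1),
                                  mu = sample(A, 1), value = rbinom(1, 1, 0.5)))
    }
  }
  fresh <- suff_stats(st$t, st$omega, st$s, h)
  expect_identical(st$counts, fresh$counts)
  expect_identical(st$G, fresh$G)
  expect_identical(st$m1, fresh$m1)
  expect_equal(sum(st$G), N)
  expect_error(update_stats(st, list(type = "membership", i = N + 1, to = 1)),
               "invalid")
})
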