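test_that("single-step decision rule satisfies its closed-form identities", {
  par <- trace_params(q = 0.05, decay = 1, sigma_x = 0.1, sigma_B = 0.05,
                      sigma_C = 1)
  dt <- 0.2
  prev <- list(s = 0L, c = 2, b = 0.5)
  cstar <- prev$c * exp(-par$decay * dt)

  # perfectly predicted observation -> no onset, transient decays exactly
  st <- hmm_step(prev, x_k = cstar + prev$b, par, dt)
  expect_identical(st$s, 0L)
  expect_equal(st$c, cstar)
  expect_equal(st$b, prev$b, tolerance = 1e-9)

  # sigma_B -> 0 limit: baseline frozen at its previous value
  par0 <- trace_params(q = 0.05, decay = 1, sigma_x = 0.1, sigma_B = 1e-9,
                       sigma_C = 1)
  st0 <- hmm_step(prev, x_k = cstar + prev$b + 0.05, par0, dt)
  expect_equal(st0$b, prev$b, tolerance = 1e-6)

  # a large unexplained jump triggers an onset that absorbs the residual
  stj <- hmm_step(prev, x_k = cstar + prev$b + 3, par, dt)
  expect_identical(stj$s, 1L)
  expect_lt(abs(stj$c + stj$b - (cstar + prev$b + 3)), 0.2)
})

test_that("R step rule and the sequential decomposition agree", {
  par <- trace_params(q = 0.05, decay = 1.5, sigma_x = 0.05, sigma_B = 0.01,
                      sigma_C = 1)
  dt <- 0.25
  sim <- simulate_trace(200, par, dt, seed = 41)
  dec <- decompose_trace(sim$x, par, dt)
  prev <- list(s = 0L, c = 0, b = sim$x[1])
  for (k in 2:length(sim$x)) {
    prev <- hmm_step(prev, sim$x[k], par, dt)
    expect_equal(prev$s, dec$s[k])
    expect_equal(prev$c, dec$c[k], tolerance = 1e-12)
    expect_equal(prev$b, dec$b[k], tolerance = 1e-12)
  }
})

test_that("decomposition is deterministic, exact-decay constrained, and quiet on flat traces", {
  par <- trace_params(q = 0.02, decay = 1, sigma_x = 0.05, sigma_B = 0.01,
                      sigma_C = 1)
  dt <- 0.2
  x <- rep(3, 100)                       # constant trace, nothing to detect
  dec <- decompose_trace(x, par, dt)
  expect_true(all(dec$s == 0L))
  expect_true(all(dec$c == 0))
  expect_equal(dec$b, rep(3, 100), tolerance = 1e-9)

  sim <- simulate_trace(300, par, dt, seed = 42)
  d1 <- decompose_trace(sim$x, par, dt)
  d2 <- decompose_trace(sim$x, par, dt)
  expect_identical(d1, d2)               # pure function of (x, params)
  off <- which(d1$s[-1] == 0L) + 1L
  expect_equal(d1$c[off], d1$c[off - 1L] * exp(-par$decay * dt), tolerance = 1e-12)
  expect_error(decompose_trace(c(1, NA, 2), par, dt), "finite")
  expect_error(decompose_trace(1, par, dt), "length")
})

test_that("an isolated large transient is detected at its onset frame", {
  par <- trace_params(q = 0.01, decay = 1, sigma_x = 0.05, sigma_B = 0.001,
                      sigma_C = 1)
  dt <- 0.2
  set.seed(43)
  M <- 200; k_on <- 100
  x <- rnorm(M + 1, 0, par$sigma_x)
  amp <- 10 * par$sigma_x
  decay_tail <- amp * exp(-par$decay * dt * (0:(M - k_on + 1)))
  x[(k_on + 1):(M + 1)] <- x[(k_on + 1):(M + 1)] + decay_tail[1:(M - k_on + 1)]
  dec <- decompose_trace(x, par, dt)
  expect_equal(dec$s[k_on + 1], 1L)
  expect_lte(sum(dec$s), 3L)             # no spurious onset storm
})

test_that("raising the noise scale monotonically reduces detected onsets", {
  par <- trace_params(q = 0.1, decay = 1, sigma_x = 0.02, sigma_B = 5e-4,
                      sigma_C = 2)
  dt <- 0.2
  sim <- simulate_trace(2000, par, dt, seed = 44)
  counts <- vapply(c(1, 2, 4, 8, 16), function(f) {
    p <- trace_params(q = par$q, decay = par$decay, sigma_x = f * par$sigma_x,
                      sigma_B = par$sigma_B, sigma_C = par$sigma_C)
    sum(decompose_trace(sim$x, p, dt)$s)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("plug-in refinement: rate identity, flooring, and precondition", {
  par <- trace_params(q = 0.1, decay = 1, sigma_x = 0.02, sigma_B = 5e-4,
                      sigma_C = 2)
  dt <- 0.2
  sim <- simulate_trace(1000, par, dt, seed = 45)
  fit <- refine_params(sim$x, par, dt, n_rounds = 1)
  # q-hat equals detected onsets over recording duration at the *final* decomposition
  refit <- refine_params(sim$x, fit$params, dt, n_rounds = 1)
  expect_equal(refit$params$q,
               sum(fit$decomposition$s[-1]) / (1000 * dt), tolerance = 1e-12)
  expect_error(refine_params(sim$x, par, dt, n_rounds = 0), "n_rounds")

  # silent trace: q floored at one event per recording and flagged
  x <- rnorm(501, 5, 0.01)
  flat <- refine_params(x, trace_params(q = .01, decay = 1, sigma_x = .01,
                                        sigma_B = .001, sigma_C = 1), dt)
  expect_true(flat$flagged)
  expect_equal(flat$params$q, 1 / (500 * dt))
})

test_that("two-round refinement recovers the onset rate and detects large transients", {
  true <- trace_params(q = 0.1, decay = 1, sigma_x = 0.02, sigma_B = 5e-4,
                       sigma_C = 2)
  dt <- 0.2; M <- 5000; reps <- 30
  set.seed(46)
  qhat <- numeric(reps); hit <- 0; tot <- 0
  for (r in seq_len(reps)) {
    sim <- simulate_trace(M, true, dt)
    fit <- refine_params(sim$x, NULL, dt, n_rounds = 2)
    qhat[r] <- fit$params$q
    cstar <- sim$c[-length(sim$c)] * exp(-true$decay * dt)
    big <- which(sim$s[-1] == 1L & (sim$c[-1] - cstar) >= 5 * true$sigma_x) + 1L
    det <- which(fit$decomposition$s == 1L)
    for (k in big) { tot <- tot + 1; if (any(abs(det - k) <= 1)) hit <- hit + 1 }
  }
  expect_lt(abs(mean(qhat) - true$q), 3 * sd(qhat))
  expect_gt(hit / tot, 0.9)
})

test_that("population binarization handles matrices, lists and silent traces", {
  par <- trace_params(q = 0.1, decay = 1, sigma_x = 0.02, sigma_B = 5e-4,
                      sigma_C = 2)
  dt <- 0.2
  set.seed(47)
  xs <- replicate(3, simulate_trace(400, par, dt)$x)
  out <- binarize_population(xs, dt)
  expect_equal(dim(out$s), c(3L, 400L))
  expect_true(all(out$s %in% 0:1))
  expect_equal(nrow(out$params), 3L)
  out2 <- binarize_population(list(xs[, 1], xs[, 2]), dt)
  expect_identical(out2$s[1, ], out$s[1, ])
  expect_error(binarize_population(list(rnorm(10), rnorm(12)), dt), "equal length")

  # silent traces (noise only, unit scale) stay all-zero and are flagged; the
  # onset decision is not scale-invariant, so featureless traces are expected
  # in units where transients would be order one
  silent1 <- matrix(rnorm(301 * 2, 0, 1), 301, 2)
  sil1 <- binarize_population(silent1, dt)
  expect_equal(sum(sil1$s), 0L)
  expect_true(all(sil1$params$flagged))
})

test_that("spike times are binned at the stated width before transient detection", {
  spikes <- data.frame(neuron_id = c(1, 1, 1, 2, 2),
                       time_s = c(0.1, 0.65, 0.7, 1.3, 5.9))
  b <- bin_spikes(spikes, bin = 0.6)
  expect_equal(b$dt, 0.6)
  expect_equal(nrow(b$counts), 2L)
  expect_equal(b$counts[1, 1:2], c(1L, 2L), ignore_attr = TRUE)
  expect_equal(sum(b$counts), 5L)
  expect_equal(b$counts[2, 10], 1L, ignore_attr = TRUE)   # spike at 5.9 s
})
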