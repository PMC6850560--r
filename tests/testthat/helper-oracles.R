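# Independent oracles used across the suite: numeric quadrature of the
# uncollapsed likelihood against the priors, and exhaustive enumeration of
# tiny posteriors. These deliberately avoid the package's sufficient-statistic
# code paths.

# canonical string of the partition induced by a labeling
canon_partition <- function(t) paste(match(t, unique(t)), collapse = "")

# marginal log-likelihood by 1-D adaptive quadrature, exploiting the
# per-assembly factorization of the joint density (supports A <= 2)
quad_marginal <- function(t, omega, s, h) {
  A <- ncol(omega); M <- nrow(omega)
  ll <- 0
  for (mu in seq_len(A)) {
    m1 <- sum(omega[, mu])
    f_p <- stats::integrate(function(p) p^m1 * (1 - p)^(M - m1) *
                              stats::dbeta(p, h$alpha_p, h$beta_p),
                            0, 1, rel.tol = 1e-12)$value
    idx <- which(t == mu)
    n11 <- sum(s[idx, omega[, mu] == 1, drop = FALSE])
    n10 <- length(idx) * m1 - n11
    n01 <- sum(s[idx, omega[, mu] == 0, drop = FALSE])
    n00 <- length(idx) * (M - m1) - n01
    f_l1 <- stats::integrate(function(l) l^n11 * (1 - l)^n10 *
                               stats::dbeta(l, h$alpha_lambda1, h$beta_lambda1),
                             0, 1, rel.tol = 1e-12)$value
    f_l0 <- stats::integrate(function(l) l^n01 * (1 - l)^n00 *
                               stats::dbeta(l, h$alpha_lambda0, h$beta_lambda0),
                             0, 1, rel.tol = 1e-12)$value
    ll <- ll + log(f_p) + log(f_l1) + log(f_l0)
  }
  G <- tabulate(t, A)
  if (A == 2) {
    f_n <- stats::integrate(function(n1) n1^G[1] * (1 - n1)^G[2] *
                              stats::dbeta(n1, h$alpha_n, h$alpha_n),
                            0, 1, rel.tol = 1e-12)$value
    ll <- ll + log(f_n)
  } else if (A != 1) stop("quadrature oracle supports A <= 2")
  ll
}

# all omega matrices for M frames x A assemblies
all_omegas <- function(M, A) {
  g <- as.matrix(expand.grid(rep(list(0:1), M * A)))
  lapply(seq_len(nrow(g)), function(r) matrix(as.integer(g[r, ]), M, A))
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# exact posterior over partitions for fixed A, summing the collapsed marginal
# over every omega configuration
enum_posterior_fixedA <- function(s, h, A) {
  M <- ncol(s); N <- nrow(s)
  tgrid <- as.matrix(expand.grid(rep(list(seq_len(A)), N)))
  oms <- all_omegas(M, A)
  lp <- vapply(seq_len(nrow(tgrid)), function(r) {
    logsumexp(vapply(oms, function(om)
      marginal_log_likelihood(tgrid[r, ], om, s, h), numeric(1)))
  }, numeric(1))
  w <- exp(lp - logsumexp(lp))
  tapply(w, vapply(seq_len(nrow(tgrid)), function(r)
    canon_partition(tgrid[r, ]), character(1)), sum)
}

# all set partitions of n elements as canonical label vectors
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, b)
  }
  out
}

# exact posterior over partitions under the CRP prior (DP mode)
enum_posterior_dp <- function(s, h) {
  N <- nrow(s); M <- ncol(s)
  parts <- set_partitions(N)
  lp <- vapply(parts, function(t) {
    A <- max(t)
    logsumexp(vapply(all_omegas(M, A), function(om)
      marginal_log_likelihood(t, om, s, h, t_prior = "dp"), numeric(1)))
  }, numeric(1))
  w <- exp(lp - logsumexp(lp))
  names(w) <- vapply(parts, paste, character(1), collapse = "")
  w
}

# brute-force pairwise co-assignment performance over all pairs
brute_rho <- function(candidate, truth) {
  as_set <- function(m) if (is.list(m)) m else as.list(m)
  ca <- as_set(candidate); tr <- as_set(truth)
  N <- length(ca)
  tot <- 0; K <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    a <- if (length(intersect(ca[[i]], ca[[j]])) > 0) 1 else -1
    b <- if (length(intersect(tr[[i]], tr[[j]])) > 0) 1 else -1
    tot <- tot + a * b; K <- K + 1
  }
  tot / K
}

rand_instance <- function(N, M, A, dens = 0.4) {
  list(t = sample.int(A, N, replace = TRUE),
       omega = matrix(rbinom(M * A, 1, 0.5), M, A),
       s = matrix(rbinom(N * M, 1, dens), N, M))
}
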