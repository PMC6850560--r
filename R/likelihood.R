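# Collapsed likelihood machinery: sufficient statistics, the joint and
# marginal log-likelihoods, and the single-site conditional distributions the
# samplers are built from. All Beta-function arithmetic is in log space
# (lgamma); co-occurrence tables reach N*M scale and would overflow otherwise.

lmvbeta <- function(a) sum(lgamma(a)) - lgamma(sum(a))

log_bern <- function(x, p) {
  out <- numeric(length(x))
  one <- x == 1L
  out[one] <- log(p[one])
  out[!one] <- log1p(-p[!one])
  out
}

#' Sufficient statistics of the collapsed assembly model
#'
#' Computes the count tables that make every sampler conditional an O(1)
#' evaluation: per-assembly sizes \code{G}, on-frame counts \code{m1} (so the
#' prior-offset frame counts are \code{H = m1 + alpha_p} and \code{Hbar =
#' M - m1 + beta_p}), and the 2x2 co-occurrence tables \code{T[mu, z, s']}
#' counting frames/neurons with (assembly state, neuron state) = (z, s'),
#' offset by the corresponding Beta prior parameters.
#'
#' The returned object also stores \code{t}, \code{omega} and \code{s} so that
#' \code{\link{update_stats}} can maintain the tables incrementally under
#' single-site moves.
#'
#' @param t integer membership vector (labels in 1..A).
#' @param omega M x A binary assembly-state matrix.
#' @param s N x M binary activity matrix.
#' @param hyper an \code{\link{assembly_hyper}}.
#' @return An object of class \code{assembly_stats}.
#' @export
suff_stats <- function(t, omega, s, hyper = assembly_hyper()) {
  st <- check_state(t, omega, s)
  A <- st$A
  G <- tabulate(st$t, nbins = A)
  m1 <- colSums(st$omega)
  # raw co-occurrence counts: cnt[mu, z+1, s'+1]
  cnt <- array(0L, dim = c(A, 2L, 2L))
  son <- st$s %*% st$omega                      # N x A: frames on & neuron active
  r <- rowSums(st$s)
  for (mu in seq_len(A)) {
    idx <- which(st$t == mu)
    a1 <- sum(son[idx, mu])                     # z=1, s=1
    atot <- sum(r[idx])
    cnt[mu, 2L, 2L] <- a1
    cnt[mu, 2L, 1L] <- G[mu] * m1[mu] - a1
    cnt[mu, 1L, 2L] <- atot - a1
    cnt[mu, 1L, 1L] <- G[mu] * (st$M - m1[mu]) - (atot - a1)
  }
  structure(list(G = G, m1 = m1, counts = cnt,
                 t = st$t, omega = st$omega, s = st$s,
                 N = st$N, M = st$M, A = A, hyper = hyper),
            class = "assembly_stats")
}

# prior-offset tables per Eq-8/Eq-9 conventions
stats_H <- function(stats) stats$m1 + stats$hyper$alpha_p
stats_Hbar <- function(stats) stats$M - stats$m1 + stats$hyper$beta_p
stats_T <- function(stats) {
  h <- stats$hyper
  gam <- matrix(c(h$beta_lambda0, h$beta_lambda1,    # s'=0 column, z=0/1 rows
                  h$alpha_lambda0, h$alpha_lambda1), 2L, 2L)
  sweep_arr <- stats$counts
  for (z in 1:2) for (sp in 1:2)
    sweep_arr[, z, sp] <- sweep_arr[, z, sp] + gam[z, sp]
  sweep_arr
}

#' Incrementally update sufficient statistics under a single-site move
#'
#' Applies one elementary state change -- reassigning a neuron's membership or
#' flipping one assembly-state entry -- and updates all count tables in O(1)
#' (plus the O(M) or O(N) scan of the affected row/column). The result is
#' bit-exact against recomputation with \code{\link{suff_stats}}.
#'
#' @param stats an \code{assembly_stats} object.
#' @param move a list; either \code{list(type = "membership", i = neuron,
#'   to = assembly)} or \code{list(type = "omega", k = frame, mu = assembly,
#'   value = 0 or 1)}.
#' @return The updated \code{assembly_stats} object.
#' @export
update_stats <- function(stats, move) {
  stopifnot(inherits(stats, "assembly_stats"), is.list(move))
  if (identical(move$type, "membership")) {
    i <- as.integer(move$i); to <- as.integer(move$to)
    if (i < 1L || i > stats$N || to < 1L || to > stats$A)
      stop("move references invalid indices")
    from <- stats$t[i]
    if (from == to) return(stats)
    srow <- stats$s[i, ]
    r <- sum(srow)
    for (mu in c(from, to)) {
      a1 <- sum(srow * stats$omega[, mu])
      d <- if (mu == from) -1L else 1L
      stats$G[mu] <- stats$G[mu] + d
      stats$counts[mu, 2L, 2L] <- stats$counts[mu, 2L, 2L] + d * a1
      stats$counts[mu, 2L, 1L] <- stats$counts[mu, 2L, 1L] + d * (stats$m1[mu] - a1)
      stats$counts[mu, 1L, 2L] <- stats$counts[mu, 1L, 2L] + d * (r - a1)
      stats$counts[mu, 1L, 1L] <- stats$counts[mu, 1L, 1L] +
        d * (stats$M - stats$m1[mu] - (r - a1))
    }
    stats$t[i] <- to
  } else if (identical(move$type, "omega")) {
    k <- as.integer(move$k); mu <- as.integer(move$mu)
    v <- as.integer(move$value)
    if (k < 1L || k > stats$M || mu < 1L || mu > stats$A || !(v %in% 0:1))
      stop("move references invalid indices")
    old <- stats$omega[k, mu]
    if (old == v) return(stats)
    idx <- stats$t == mu
    c_on <- sum(stats$s[idx, k])
    g <- stats$G[mu]
    zo <- old + 1L; zn <- v + 1L
    stats$counts[mu, zo, 2L] <- stats$counts[mu, zo, 2L] - c_on
    stats$counts[mu, zo, 1L] <- stats$counts[mu, zo, 1L] - (g - c_on)
    stats$counts[mu, zn, 2L] <- stats$counts[mu, zn, 2L] + c_on
    stats$counts[mu, zn, 1L] <- stats$counts[mu, zn, 1L] + (g - c_on)
    stats$m1[mu] <- stats$m1[mu] + (v - old)
    stats$omega[k, mu] <- v
  } else stop("unknown move type")
  stats
}

#' Joint log-likelihood of the uncollapsed model
#'
#' Evaluates \eqn{\log P(t, \omega, s \mid \theta)}: the product of the
#' categorical membership term, the Bernoulli assembly-state term, and the
#' conditional Bernoulli firing term, in log space. Events of probability
#' zero yield \code{-Inf}, never an error.
#'
#' @inheritParams suff_stats
#' @param params an \code{\link{assembly_model}} (A must equal ncol(omega)).
#' @return A single log-probability.
#' @export
full_log_likelihood <- function(t, omega, s, params) {
  stopifnot(inherits(params, "assembly_model"))
  st <- check_state(t, omega, s)
  if (params$A != st$A) stop("params$A must match ncol(omega)")
  ll_t <- sum(log(params$n[st$t]))
  pmat <- rep(params$p, each = st$M)
  ll_omega <- sum(log_bern(as.vector(st$omega), pmat))
  zmat <- st$omega[, st$t, drop = FALSE]              # M x N
  lam <- ifelse(zmat == 1L, rep(params$lambda1[st$t], each = st$M),
                rep(params$lambda0[st$t], each = st$M))
  ll_s <- sum(log_bern(as.vector(t(st$s)), as.vector(lam)))
  ll_t + ll_omega + ll_s
}

#' Marginal log-likelihood of the collapsed model
#'
#' Evaluates \eqn{\log P(t, \omega, s)} after analytically integrating the
#' continuous parameters (p, lambda, n) against their conjugate Beta /
#' Dirichlet priors; the result is a product of Beta-function ratios over the
#' sufficient statistics. With \code{t_prior = "dp"} the Dirichlet-multinomial
#' membership term is replaced by the Chinese-restaurant-process probability
#' of the induced partition (empty assemblies are not allowed in this mode).
#'
#' @inheritParams suff_stats
#' @param t_prior \code{"dirichlet"} (fixed-A) or \code{"dp"}.
#' @return A single log-probability.
#' @export
marginal_log_likelihood <- function(t, omega, s, hyper = assembly_hyper(),
                                    t_prior = c("dirichlet", "dp")) {
  t_prior <- match.arg(t_prior)
  stopifnot(inherits(hyper, "assembly_hyper"))
  stats <- suff_stats(t, omega, s, hyper)
  marginal_from_stats(stats, t_prior)
}

marginal_from_stats <- function(stats, t_prior = "dirichlet") {
  h <- stats$hyper
  A <- stats$A
  if (t_prior == "dirichlet") {
    ll_t <- lmvbeta(stats$G + h$alpha_n) - lmvbeta(rep(h$alpha_n, A))
  } else {
    if (any(stats$G == 0L)) stop("empty assemblies are not allowed under the DP prior")
    ll_t <- A * log(h$dp_alpha) + sum(lgamma(stats$G)) +
      lgamma(h$dp_alpha) - lgamma(h$dp_alpha + stats$N)
  }
  ll_omega <- sum(lbeta(stats$m1 + h$alpha_p, stats$M - stats$m1 + h$beta_p)) -
    A * lbeta(h$alpha_p, h$beta_p)
  Tt <- stats_T(stats)
  ll_s <- sum(lbeta(Tt[, 1L, 2L], Tt[, 1L, 1L])) -
    A * lbeta(h$alpha_lambda0, h$beta_lambda0) +
    sum(lbeta(Tt[, 2L, 2L], Tt[, 2L, 1L])) -
    A * lbeta(h$alpha_lambda1, h$beta_lambda1)
  ll_t + ll_omega + ll_s
}

#' Conditional probability of one assembly-state entry
#'
#' Probability that \code{omega[k, mu] = 1} given everything else, under the
#' collapsed model. Derived directly from the marginal likelihood: the
#' prior-odds factor uses the on/off frame counts with frame \code{k} removed,
#' and the likelihood factor is the Beta-function ratio obtained by moving the
#' frame's member-activity counts between the off and on rows of the
#' co-occurrence table.
#'
#' @inheritParams suff_stats
#' @param k frame index.
#' @param mu assembly index.
#' @return Probability in [0,1].
#' @export
omega_conditional <- function(t, omega, s, hyper = assembly_hyper(), k, mu) {
  stats <- suff_stats(t, omega, s, hyper)
  h <- hyper
  M <- stats$M
  z_cur <- stats$omega[k, mu]
  g <- stats$G[mu]
  c_on <- if (g > 0L) sum(stats$s[stats$t == mu, k]) else 0L
  m1p <- stats$m1[mu] - z_cur                      # on-frames excluding site k
  cnt <- stats$counts[mu, , ]                      # rows z=0/1, cols s'=0/1
  cnt[z_cur + 1L, 2L] <- cnt[z_cur + 1L, 2L] - c_on
  cnt[z_cur + 1L, 1L] <- cnt[z_cur + 1L, 1L] - (g - c_on)
  gam <- matrix(c(h$beta_lambda0, h$beta_lambda1,
                  h$alpha_lambda0, h$alpha_lambda1), 2L, 2L)
  base <- cnt + gam
  logR <- log(m1p + h$alpha_p) - log(M - 1 - m1p + h$beta_p) +
    lbeta(base[2L, 2L] + c_on, base[2L, 1L] + g - c_on) -
    lbeta(base[2L, 2L], base[2L, 1L]) -
    (lbeta(base[1L, 2L] + c_on, base[1L, 1L] + g - c_on) -
       lbeta(base[1L, 2L], base[1L, 1L]))
  stats::plogis(logR)
}

#' Conditional membership distribution of one neuron (fixed A)
#'
#' Categorical conditional \eqn{P(t_i = \mu \mid t_{-i}, \omega, s)} for all
#' assemblies, using leave-one-out co-occurrence tables: the weight of
#' assembly mu is the leave-one-out occupancy plus the Dirichlet weight, times
#' the Beta-function ratio of the table with and without neuron i.
#'
#' @inheritParams suff_stats
#' @param i neuron index.
#' @return Numeric vector of length A summing to 1.
#' @export
membership_conditional <- function(t, omega, s, hyper = assembly_hyper(), i) {
  stats <- suff_stats(t, omega, s, hyper)
  h <- hyper
  logw <- membership_logweights(stats, i, h$alpha_n)
  w <- exp(logw - max(logw))
  w / sum(w)
}

# leave-one-out log-weights for neuron i over all current assemblies;
# prior_w is added to the leave-one-out occupancy (alpha_n or G for CRP)
membership_logweights <- function(stats, i, prior_w) {
  h <- stats$hyper
  M <- stats$M
  cur <- stats$t[i]
  srow <- stats$s[i, ]
  r <- sum(srow)
  gam <- matrix(c(h$beta_lambda0, h$beta_lambda1,
                  h$alpha_lambda0, h$alpha_lambda1), 2L, 2L)
  vapply(seq_len(stats$A), function(mu) {
    a1 <- sum(srow * stats$omega[, mu])
    m1 <- stats$m1[mu]
    add <- matrix(c(M - m1 - (r - a1), m1 - a1, r - a1, a1), 2L, 2L)
    cnt <- stats$counts[mu, , ]
    if (mu == cur) cnt <- cnt - add                 # leave-one-out table
    base <- cnt + gam
    gloo <- stats$G[mu] - (mu == cur)
    log(gloo + prior_w) +
      lbeta(base[2L, 2L] + a1, base[2L, 1L] + m1 - a1) -
      lbeta(base[2L, 2L], base[2L, 1L]) +
      lbeta(base[1L, 2L] + r - a1, base[1L, 1L] + (M - m1) - (r - a1)) -
      lbeta(base[1L, 2L], base[1L, 1L])
  }, numeric(1))
}

#' Draw model parameters from their conditional posterior
#'
#' Given the latent state, draws \code{p}, \code{lambda0}, \code{lambda1} from
#' Beta distributions and \code{n} from a Dirichlet distribution with the
#' posterior hyperparameters implied by the sufficient statistics. These
#' draws are posterior readouts; the collapsed sampler conditionals never
#' depend on them.
#'
#' @inheritParams suff_stats
#' @return An \code{\link{assembly_model}} draw.
#' @export
sample_theta <- function(t, omega, s, hyper = assembly_hyper()) {
  stats <- suff_stats(t, omega, s, hyper)
  h <- hyper
  A <- stats$A
  Tt <- stats_T(stats)
  p <- stats::rbeta(A, stats$m1 + h$alpha_p, stats$M - stats$m1 + h$beta_p)
  lambda0 <- stats::rbeta(A, Tt[, 1L, 2L], Tt[, 1L, 1L])
  lambda1 <- stats::rbeta(A, Tt[, 2L, 2L], Tt[, 2L, 1L])
  g <- stats::rgamma(A, shape = stats$G + h$alpha_n)
  assembly_model(n = g / sum(g), p = pmin(pmax(p, 1e-12), 1 - 1e-12),
                 lambda0 = lambda0, lambda1 = lambda1)
}
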