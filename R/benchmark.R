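#' Generate a benchmark dataset with multi-membership neurons
#'
#' Simulates binary population activity where a stated fraction of neurons
#' belongs to more than one assembly. Single-membership neurons follow the
#' generative model exactly; a multi-membership neuron is recruited by any of
#' its assemblies, firing at frame k with probability
#' \eqn{1 - \prod_a (1 - \lambda_a(\omega_{ka}))} over its assemblies a
#' (a noisy-OR across assemblies). With \code{frac_multi = 0} the generator
#' reduces to the single-membership model.
#'
#' @param N,M,A neurons, frames, assemblies.
#' @param frac_multi fraction of neurons with multiple memberships.
#' @param max_memberships cap on memberships per neuron (>= 2).
#' @param p,lambda1,lambda0 per-assembly activity, synchrony and asynchrony
#'   (recycled to length A). Defaults are the benchmark conditions: 400
#'   neurons, 1000 frames, 5 assemblies, activity 5\%, synchrony 50\%,
#'   asynchrony 10\%, with 20\% of neurons in up to 2 assemblies.
#' @param seed optional integer seed.
#' @return A list with \code{s} (N x M matrix), \code{membership} (list of
#'   integer vectors, one set of assembly labels per neuron), \code{omega}
#'   and \code{params}.
#' @export
generate_multi <- function(N = 400, M = 1000, A = 5, frac_multi = 0.2,
                           max_memberships = 2, p = 0.05, lambda1 = 0.5,
                           lambda0 = 0.1, seed = NULL) {
  stopifnot(N >= 1, M >= 1, A >= 1, frac_multi >= 0, frac_multi <= 1,
            max_memberships >= 2)
  if (!is.null(seed)) set.seed(seed)
  p <- rep_len(p, A); lambda1 <- rep_len(lambda1, A); lambda0 <- rep_len(lambda0, A)
  omega <- matrix(stats::rbinom(M * A, 1L, rep(p, each = M)), M, A)
  n_multi <- round(frac_multi * N)
  multi <- if (n_multi > 0) sample.int(N, n_multi) else integer(0)
  membership <- vector("list", N)
  base <- sample.int(A, N, replace = TRUE)
  for (i in seq_len(N)) membership[[i]] <- base[i]
  for (i in multi) {
    extra <- sample.int(max_memberships - 1L, 1L)
    pool <- setdiff(seq_len(A), base[i])
    membership[[i]] <- c(base[i], sample(pool, min(extra, length(pool))))
  }
  s <- matrix(0L, N, M)
  for (i in seq_len(N)) {
    mus <- membership[[i]]
    lam <- matrix(0, M, length(mus))
    for (j in seq_along(mus)) {
      mu <- mus[j]
      lam[, j] <- ifelse(omega[, mu] == 1L, lambda1[mu], lambda0[mu])
    }
    pr <- 1 - apply(1 - lam, 1L, prod)
    s[i, ] <- stats::rbinom(M, 1L, pr)
  }
  list(s = s, membership = membership, omega = omega,
       params = list(p = p, lambda1 = lambda1, lambda0 = lambda0))
}

as_membership_sets <- function(m) {
  if (is.list(m)) lapply(m, function(v) as.integer(v))
  else lapply(as.integer(m), function(v) v)
}

#' Pairwise co-assignment performance
#'
#' Compares a candidate membership map against the ground truth through their
#' pairwise assignment matrices: entry (i, j) is +1 when neurons i and j share
#' at least one assembly and -1 otherwise (the set-intersection rule handles
#' multi-membership maps). The performance is the normalized inner product of
#' the two matrices over the K = N(N-1)/2 neuron pairs, so identical
#' partitions score 1, total pairwise disagreement scores -1, and the value is
#' invariant under relabeling of either side. Neurons assigned to no assembly
#' are treated as singleton clusters.
#'
#' @param candidate membership vector, or list of per-neuron label sets.
#' @param truth ground-truth membership vector or list of label sets.
#' @return The performance rho in [-1, 1].
#' @examples
#' performance(c(1, 1, 2, 2), c(1, 1, 2, 2))   # 1
#' performance(c(1, 2, 1, 2), c(1, 1, 2, 2))   # -1/3
#' @export
performance <- function(candidate, truth) {
  ca <- as_membership_sets(candidate)
  tr <- as_membership_sets(truth)
  if (length(ca) != length(tr))
    stop("candidate and truth must cover the same neurons")
  N <- length(ca)
  if (N < 2L) stop("need at least two neurons")
  # free neurons (empty sets) become singletons: give each a unique label
  nxt <- -1L
  for (i in seq_len(N)) {
    if (length(ca[[i]]) == 0L) { ca[[i]] <- nxt; nxt <- nxt - 1L }
    if (length(tr[[i]]) == 0L) { tr[[i]] <- nxt; nxt <- nxt - 1L }
  }
  Ic <- pairwise_assignment(ca)
  It <- pairwise_assignment(tr)
  K <- N * (N - 1) / 2
  sum(Ic[upper.tri(Ic)] * It[upper.tri(It)]) / K
}

#' Pairwise assignment matrix of a membership map
#'
#' @param membership membership vector or list of per-neuron label sets.
#' @return N x N matrix with +1 where memberships intersect, -1 otherwise
#'   (diagonal +1, ignored by \code{\link{performance}}).
#' @export
pairwise_assignment <- function(membership) {
  m <- as_membership_sets(membership)
  N <- length(m)
  single <- all(lengths(m) == 1L)
  if (single) {
    v <- vapply(m, `[[`, integer(1), 1L)
    I <- outer(v, v, "==")
  } else {
    I <- matrix(FALSE, N, N)
    for (i in seq_len(N)) for (j in seq_len(N))
      I[i, j] <- length(intersect(m[[i]], m[[j]])) > 0L
  }
  matrix(ifelse(I, 1L, -1L), N, N)
}

#' Detectability phase grid
#'
#' Maps the detectable / non-detectable regimes of the model: for each
#' (asynchrony, synchrony) grid cell, simulates equal-size assemblies, runs
#' the Dirichlet-process sampler, and records whether the final sample
#' recovers the planted partition exactly (performance rho = 1) together with
#' the mean membership transition rate over the last sweeps.
#'
#' @param lambda0_values,lambda1_values grid values in (0, 1).
#' @param p assembly activation probability.
#' @param N,M,A problem size per cell.
#' @param reps replicates per cell; recovery is declared when the final
#'   sample of any replicate's converged chain has rho = 1.
#' @param n_iter sweeps per run.
#' @param seed integer seed (replicate seeds are derived from it).
#' @param hyper an \code{\link{assembly_hyper}}.
#' @return Data frame with one row per (lambda0, lambda1) cell: fraction of
#'   replicates with exact recovery, \code{detected} (TRUE when any replicate
#'   recovered exactly), the mean membership transition rate over all sweeps
#'   and replicates (the order parameter of the detectability transition), and
#'   the mean final assembly count.
#' @export
phase_grid <- function(lambda0_values, lambda1_values, p = 0.1, N = 100,
                       M = 1000, A = 5, reps = 1L, n_iter = 300,
                       seed = 1L, hyper = assembly_hyper()) {
  stopifnot(all(lambda0_values > 0 & lambda0_values < 1),
            all(lambda1_values > 0 & lambda1_values < 1))
  grid <- expand.grid(lambda0 = lambda0_values, lambda1 = lambda1_values)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    l0 <- grid$lambda0[g]; l1 <- grid$lambda1[g]
    rec <- logical(reps); rate <- numeric(reps); Af <- integer(reps)
    for (r in seq_len(reps)) {
      sd_r <- (seed + 7919L * g + 104729L * r) %% .Machine$integer.max
      mod <- assembly_model(rep(1, A), p = p, lambda0 = l0, lambda1 = l1)
      sim <- simulate_assemblies(mod, N, M, seed = sd_r, equal_sizes = TRUE)
      tr <- dp_run(sim$s, hyper = hyper, n_iter = n_iter, thin = n_iter,
                   seed = sd_r + 1L, record_omega = FALSE, record_theta = FALSE)
      rec[r] <- performance(tr$t_final, sim$t) == 1
      rate[r] <- mean(tr$trans_rate)
      Af[r] <- tr$A_final
    }
    out[[g]] <- data.frame(lambda0 = l0, lambda1 = l1,
                           recovery = mean(rec), detected = any(rec),
                           trans_rate = mean(rate), A_final = mean(Af))
  }
  do.call(rbind, out)
}

#' Score external membership assignments against a ground truth
#'
#' Scoring harness for method comparisons: computes the pairwise co-assignment
#' performance of any number of candidate assignments (this tool's or an
#' external method's) against the same ground truth.
#'
#' @param truth ground-truth membership vector or list of label sets.
#' @param ... named candidate assignments (vectors or lists of label sets).
#' @return A data frame with columns \code{method} and \code{rho}.
#' @export
compare_methods <- function(truth, ...) {
  cands <- list(...)
  if (length(cands) == 0L) stop("no candidate assignments supplied")
  if (is.null(names(cands)) || any(names(cands) == ""))
    names(cands) <- paste0("method", seq_along(cands))
  data.frame(method = names(cands),
             rho = vapply(cands, performance, numeric(1), truth = truth),
             row.names = NULL)
}
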