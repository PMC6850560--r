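#' Collapsed Gibbs sampler at a fixed number of assemblies
#'
#' Runs the collapsed Gibbs sampler: each sweep updates every assembly-state
#' entry \code{omega[k, mu]} from its two-point conditional, then every neuron
#' membership from its categorical conditional, then draws the continuous
#' parameters from their conditional posterior as readouts. Per-sweep
#' diagnostics (log marginal likelihood, membership transition rate) are
#' recorded throughout; latent-state snapshots are kept after burn-in at the
#' thinning interval.
#'
#' @param s N x M binary activity matrix (neurons x frames).
#' @param A fixed number of assemblies (>= 1).
#' @param hyper an \code{\link{assembly_hyper}}.
#' @param n_iter total number of sweeps.
#' @param burn_in sweeps discarded before snapshots are kept (default half).
#' @param thin keep every \code{thin}-th post-burn-in sweep.
#' @param seed optional integer seed.
#' @param t_init optional initial membership vector in 1..A (default uniform
#'   random).
#' @param record_omega,record_theta whether to snapshot assembly states and
#'   parameter draws (needed for posterior summaries and correlation graphs).
#' @return An object of class \code{assembly_trace}.
#' @examples
#' mod <- assembly_model(rep(1, 2), p = 0.2, lambda0 = 0.05, lambda1 = 0.8)
#' sim <- simulate_assemblies(mod, N = 20, M = 60, seed = 1)
#' tr <- gibbs_run(sim$s, A = 2, n_iter = 50, seed = 2)
#' tr$A_final
#' @export
gibbs_run <- function(s, A, hyper = assembly_hyper(), n_iter = 300,
                      burn_in = floor(n_iter / 2), thin = 1L, seed = NULL,
                      t_init = NULL, record_omega = TRUE, record_theta = TRUE) {
  s <- check_binary_matrix(s)
  stopifnot(A >= 1, n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(s)
  if (is.null(t_init)) t_init <- sample.int(A, N, replace = TRUE)
  if (length(t_init) != N || any(t_init < 1L) || any(t_init > A))
    stop("'t_init' must be a length-N vector of labels in 1..A")
  res <- .sampler_run(s, as.integer(t_init), as.integer(A), unclass(hyper),
                      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                      FALSE, record_omega, record_theta)
  new_trace(res, mode = "fixed", hyper = hyper, n_iter = n_iter,
            burn_in = burn_in, thin = thin, N = N, M = ncol(s), seed = seed)
}

#' Dirichlet-process sampler over a variable number of assemblies
#'
#' Runs the variable-A sampler: Gibbs sweeps over the assembly-state matrix
#' alternate with per-neuron Metropolis-Hastings membership moves whose
#' proposal draws existing assemblies proportionally to their occupancy and a
#' fresh assembly proportionally to the DP concentration; a fresh assembly's
#' state column is drawn from its prior and the move is accepted with the
#' collapsed likelihood ratio. Assemblies left empty are deleted. The default
#' initialization assigns each neuron a uniform label on 1..N, so the chain
#' starts from O(N) assemblies and merges them as it converges.
#'
#' @inheritParams gibbs_run
#' @param t_init optional initial membership labels (default uniform on 1..N).
#' @return An object of class \code{assembly_trace}.
#' @examples
#' mod <- assembly_model(rep(1, 2), p = 0.2, lambda0 = 0.05, lambda1 = 0.8)
#' sim <- simulate_assemblies(mod, N = 20, M = 80, seed = 1)
#' tr <- dp_run(sim$s, n_iter = 80, seed = 2)
#' tr$A_final
#' @export
dp_run <- function(s, hyper = assembly_hyper(), n_iter = 300,
                   burn_in = floor(n_iter / 2), thin = 1L, seed = NULL,
                   t_init = NULL, record_omega = TRUE, record_theta = TRUE) {
  s <- check_binary_matrix(s)
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(s)
  if (is.null(t_init)) t_init <- sample.int(N, N, replace = TRUE)
  if (length(t_init) != N || any(t_init < 1L))
    stop("'t_init' must be a length-N vector of positive labels")
  res <- .sampler_run(s, as.integer(t_init), 0L, unclass(hyper),
                      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                      TRUE, record_omega, record_theta)
  new_trace(res, mode = "dp", hyper = hyper, n_iter = n_iter,
            burn_in = burn_in, thin = thin, N = N, M = ncol(s), seed = seed)
}

new_trace <- function(res, mode, hyper, n_iter, burn_in, thin, N, M, seed) {
  if (!isTRUE(res$stats_ok))
    stop("internal error: incremental sufficient statistics diverged from batch recomputation")
  structure(list(
    t_samples = res$t_samples, omega_samples = res$omega_samples,
    theta_samples = res$theta_samples, loglik = res$loglik,
    trans_rate = res$trans_rate, A = res$A,
    t_final = res$t_final, A_final = res$A_final,
    mode = mode, hyper = hyper, n_iter = n_iter, burn_in = burn_in,
    thin = thin, N = N, M = M, seed = seed), class = "assembly_trace")
}

#' @export
print.assembly_trace <- function(x, ...) {
  cat(sprintf("Assembly sampler trace (%s mode): %d sweeps, %d saved samples\n",
              x$mode, x$n_iter, nrow(x$t_samples)))
  cat(sprintf("  N = %d neurons, M = %d frames, final A = %d\n",
              x$N, x$M, x$A_final))
  cat(sprintf("  final log marginal likelihood: %.2f, final transition rate: %.3f\n",
              x$loglik[x$n_iter], x$trans_rate[x$n_iter]))
  invisible(x)
}

#' Convergence diagnostics of a sampler trace
#'
#' Per-sweep log marginal likelihood, membership transition rate (fraction of
#' neurons reassigned during the sweep -- the order parameter separating the
#' detectable from the non-detectable regime) and assembly-count trajectory.
#' The chain is flagged converged when the transition rate stays below
#' \code{rate_threshold} for \code{window} consecutive sweeps.
#'
#' @param trace an \code{assembly_trace}.
#' @param rate_threshold convergence threshold on the transition rate
#'   (default 1/N).
#' @param window number of consecutive sub-threshold sweeps required.
#' @return A list with the per-sweep data frame, a \code{converged} flag and
#'   the first sweep at which the criterion was met (NA if never).
#' @export
diagnostics <- function(trace, rate_threshold = NULL, window = 20L) {
  stopifnot(inherits(trace, "assembly_trace"), trace$n_iter >= 2)
  if (is.null(rate_threshold)) rate_threshold <- 1 / trace$N
  d <- data.frame(iteration = seq_len(trace$n_iter), loglik = trace$loglik,
                  trans_rate = trace$trans_rate, A = trace$A)
  below <- d$trans_rate < rate_threshold
  run <- 0L; at <- NA_integer_
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= window) { at <- i - window + 1L; break }
  }
  list(sweeps = d, converged = !is.na(at), converged_at = at,
       rate_threshold = rate_threshold, window = window)
}

# Greedy alignment of one labeling against a reference partition: assemblies
# are matched in decreasing order of overlap; unmatched labels get fresh ones.
align_one <- function(labels, ref) {
  tab <- table(labels, ref)
  ids <- rownames(tab); refs <- colnames(tab)
  map <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  used <- logical(length(refs))
  tm <- as.matrix(tab)
  repeat {
    if (all(!is.na(map)) || all(used)) break
    best <- which(tm == max(tm), arr.ind = TRUE)[1, , drop = TRUE]
    if (tm[best[1], best[2]] <= 0) break
    map[ids[best[1]]] <- as.integer(refs[best[2]])
    used[best[2]] <- TRUE
    tm[best[1], ] <- -1L
    tm[, best[2]] <- -1L
  }
  nxt <- max(as.integer(refs)) + 1L
  for (j in which(is.na(map))) { map[j] <- nxt; nxt <- nxt + 1L }
  map
}

#' Align posterior samples to a common labeling
#'
#' Assembly labels are arbitrary within each posterior sample. This relabels
#' every saved sample by greedy overlap matching against a reference partition
#' (by default the saved sample with the highest log marginal likelihood), so
#' that per-assembly quantities can be averaged across samples.
#'
#' @param trace an \code{assembly_trace}.
#' @param reference optional reference membership vector; default is the saved
#'   sample at the maximum-likelihood sweep.
#' @return A list with \code{aligned} (samples x neurons matrix of aligned
#'   labels), \code{reference}, and \code{maps} (per-sample label maps, used to
#'   align omega and theta snapshots).
#' @export
align_trace <- function(trace, reference = NULL) {
  stopifnot(inherits(trace, "assembly_trace"))
  ts <- trace$t_samples
  if (nrow(ts) < 1L) stop("trace holds no saved samples")
  if (is.null(reference)) {
    saved_iters <- seq(trace$burn_in + 1L, trace$n_iter, by = trace$thin)
    saved_iters <- saved_iters[seq_len(nrow(ts))]
    reference <- ts[which.max(trace$loglik[saved_iters]), ]
  }
  reference <- match(reference, sort(unique(reference)))  # canonical 1..A
  aligned <- matrix(NA_integer_, nrow(ts), ncol(ts))
  maps <- vector("list", nrow(ts))
  for (r in seq_len(nrow(ts))) {
    map <- align_one(ts[r, ], reference)
    aligned[r, ] <- map[as.character(ts[r, ])]
    maps[[r]] <- map
  }
  list(aligned = aligned, reference = reference, maps = maps)
}

#' Posterior membership of each neuron
#'
#' After label alignment, reports each neuron's modal assembly and the
#' fraction of post-burn-in samples supporting it (the membership confidence).
#'
#' @param trace an \code{assembly_trace}.
#' @param alignment optional result of \code{\link{align_trace}}.
#' @return A data frame with columns \code{neuron}, \code{assembly},
#'   \code{confidence}.
#' @export
membership_posterior <- function(trace, alignment = NULL) {
  if (is.null(alignment)) alignment <- align_trace(trace)
  al <- alignment$aligned
  modal <- integer(ncol(al)); conf <- numeric(ncol(al))
  for (i in seq_len(ncol(al))) {
    tb <- table(al[, i])
    j <- which.max(tb)
    modal[i] <- as.integer(names(tb)[j])
    conf[i] <- tb[j] / nrow(al)
  }
  data.frame(neuron = seq_len(ncol(al)), assembly = modal, confidence = conf)
}

# The likelihood is exactly invariant under inverting one assembly's state
# column while swapping lambda(0) <-> lambda(1) and p <-> 1-p; with symmetric
# priors each assembly freezes in one of the two equivalent orientations.
# Summaries report the sparse-activity representative (p < 1/2), the
# convention the feature filters and the field's "activity" semantics assume.
canon_theta <- function(th) {
  flip <- th$p > 0.5
  if (any(flip)) {
    p <- th$p; l0 <- th$lambda0; l1 <- th$lambda1
    th$p[flip] <- 1 - p[flip]
    th$lambda0[flip] <- l1[flip]
    th$lambda1[flip] <- l0[flip]
  }
  th
}

canon_omega <- function(om) {
  flip <- colMeans(om) > 0.5
  if (any(flip)) om[, flip] <- 1L - om[, flip, drop = FALSE]
  om
}

#' Posterior summaries of assembly features
#'
#' Aligned posterior means of the per-assembly parameters: activity \code{p},
#' asynchrony \code{lambda0}, synchrony \code{lambda1} and size \code{G},
#' together with the fraction of samples in which the assembly appears. These
#' are the feature estimates the assembly-selection filter operates on.
#' Each assembly is reported in its sparse-activity orientation (activity
#' below 1/2): the model cannot distinguish an assembly from its on/off
#' inverse, so the representative active in the minority of frames is chosen.
#'
#' @inheritParams membership_posterior
#' @return A data frame with one row per aligned assembly.
#' @export
assembly_summary <- function(trace, alignment = NULL) {
  stopifnot(inherits(trace, "assembly_trace"))
  if (length(trace$theta_samples) == 0L)
    stop("trace was run with record_theta = FALSE")
  if (is.null(alignment)) alignment <- align_trace(trace)
  acc <- list()
  for (r in seq_along(trace$theta_samples)) {
    th <- canon_theta(trace$theta_samples[[r]])
    lab <- alignment$maps[[r]][as.character(th$id)]
    acc[[r]] <- data.frame(assembly = lab, G = th$G, p = th$p,
                           lambda0 = th$lambda0, lambda1 = th$lambda1)
  }
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(cbind(G, p, lambda0, lambda1) ~ assembly, all, mean)
  agg$n_samples <- as.vector(table(factor(all$assembly, levels = agg$assembly)))
  agg$support <- agg$n_samples / length(trace$theta_samples)
  agg[order(agg$assembly), ]
}

#' Posterior mean of the assembly activity matrix
#'
#' Averages the aligned assembly-state snapshots across post-burn-in samples,
#' after flipping each column to its sparse-activity orientation (see
#' \code{\link{assembly_summary}}).
#'
#' @inheritParams membership_posterior
#' @return An M x A matrix of posterior on-probabilities, columns named by
#'   aligned assembly label.
#' @export
omega_posterior_mean <- function(trace, alignment = NULL) {
  stopifnot(inherits(trace, "assembly_trace"))
  if (length(trace$omega_samples) == 0L)
    stop("trace was run with record_omega = FALSE")
  if (is.null(alignment)) alignment <- align_trace(trace)
  labs <- sort(unique(unlist(lapply(seq_along(trace$omega_samples), function(r) {
    ids <- attr(trace$omega_samples[[r]], "assembly_id")
    unname(alignment$maps[[r]][as.character(ids)])
  }))))
  out <- matrix(0, trace$M, length(labs), dimnames = list(NULL, labs))
  cnt <- numeric(length(labs))
  for (r in seq_along(trace$omega_samples)) {
    om <- trace$omega_samples[[r]]
    ids <- attr(om, "assembly_id")
    lab <- alignment$maps[[r]][as.character(ids)]
    om <- canon_omega(om)
    for (j in seq_along(lab)) {
      col <- match(lab[j], labs)
      out[, col] <- out[, col] + om[, j]
      cnt[col] <- cnt[col] + 1
    }
  }
  sweep(out, 2L, pmax(cnt, 1), "/")
}
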