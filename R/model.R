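#' Assembly model parameters
#'
#' Container for the parameters of the hierarchical Bernoulli model of
#' assembly activity: each of \code{A} assemblies has a relative size
#' \code{n[mu]} (a point on the simplex), a per-frame activation probability
#' \code{p[mu]}, and two conditional firing probabilities for its member
#' neurons: \code{lambda0[mu]} when the assembly is off (asynchrony) and
#' \code{lambda1[mu]} when it is on (synchrony).
#'
#' @param n numeric vector of relative assembly sizes; normalized to sum to 1.
#' @param p per-assembly activation probabilities in (0,1) (recycled).
#' @param lambda0 per-assembly asynchronous firing probabilities in [0,1].
#' @param lambda1 per-assembly synchronous firing probabilities in [0,1].
#' @return An object of class \code{assembly_model}.
#' @examples
#' assembly_model(n = rep(1, 5), p = 0.1, lambda0 = 0.08, lambda1 = 0.6)
#' @export
assembly_model <- function(n, p, lambda0, lambda1) {
  A <- length(n)
  if (A < 1L || any(!is.finite(n)) || any(n <= 0))
    stop("'n' must be positive relative sizes")
  n <- n / sum(n)
  p <- rep_len(p, A); lambda0 <- rep_len(lambda0, A); lambda1 <- rep_len(lambda1, A)
  for (nm in c("p")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0) || any(v >= 1))
      stop(sprintf("'%s' must lie strictly in (0,1)", nm))
  }
  for (nm in c("lambda0", "lambda1")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop(sprintf("'%s' must lie in [0,1]", nm))
  }
  structure(list(n = n, p = p, lambda0 = lambda0, lambda1 = lambda1, A = A),
            class = "assembly_model")
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("Assembly model with A = %d assemblies\n", x$A))
  print(data.frame(n = x$n, p = x$p, lambda0 = x$lambda0, lambda1 = x$lambda1))
  invisible(x)
}

#' Hyperparameters of the collapsed model
#'
#' Beta priors on the assembly activation probability \code{p} and on the
#' conditional firing probabilities \code{lambda(z)}, a symmetric Dirichlet
#' prior on relative assembly sizes (fixed-A mode), and the Dirichlet-process
#' concentration (variable-A mode). Defaults are uninformative Beta(1,1) /
#' Dirichlet(1) with unit DP concentration.
#'
#' @param alpha_p,beta_p Beta prior on p.
#' @param alpha_lambda0,beta_lambda0 Beta prior on lambda(0) (asynchrony).
#' @param alpha_lambda1,beta_lambda1 Beta prior on lambda(1) (synchrony).
#' @param alpha_n symmetric Dirichlet weight on assembly sizes (fixed-A mode).
#' @param dp_alpha Dirichlet-process concentration (variable-A mode).
#' @return An object of class \code{assembly_hyper}.
#' @export
assembly_hyper <- function(alpha_p = 1, beta_p = 1,
                           alpha_lambda0 = 1, beta_lambda0 = 1,
                           alpha_lambda1 = 1, beta_lambda1 = 1,
                           alpha_n = 1, dp_alpha = 1) {
  h <- list(alpha_p = alpha_p, beta_p = beta_p,
            alpha_lambda0 = alpha_lambda0, beta_lambda0 = beta_lambda0,
            alpha_lambda1 = alpha_lambda1, beta_lambda1 = beta_lambda1,
            alpha_n = alpha_n, dp_alpha = dp_alpha)
  if (any(!vapply(h, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, logical(1))))
    stop("all hyperparameters must be single strictly positive numbers")
  structure(h, class = "assembly_hyper")
}

check_binary_matrix <- function(s) {
  if (!is.matrix(s) || nrow(s) < 1L || ncol(s) < 1L)
    stop("'s' must be a neuron x frame matrix with N >= 1, M >= 1")
  if (anyNA(s) || !all(s == 0L | s == 1L))
    stop("'s' must contain only 0/1 entries with no missing values")
  storage.mode(s) <- "integer"
  s
}

check_state <- function(t, omega, s) {
  s <- check_binary_matrix(s)
  N <- nrow(s); M <- ncol(s)
  if (length(t) != N) stop("length(t) must equal nrow(s)")
  if (!is.matrix(omega) || nrow(omega) != M)
    stop("'omega' must be an M x A matrix")
  if (anyNA(omega) || !all(omega == 0L | omega == 1L))
    stop("'omega' must contain only 0/1 entries")
  A <- ncol(omega)
  if (any(t < 1L) || any(t > A)) stop("membership labels must lie in 1..A")
  list(t = as.integer(t), omega = matrix(as.integer(omega), M, A), s = s,
       N = N, M = M, A = A)
}

#' Simulate an activity matrix from the generative model
#'
#' Draws a dataset by the model's three generative steps: memberships
#' \code{t[i]} from a categorical distribution with probabilities \code{n};
#' assembly states \code{omega[k, mu]} i.i.d. Bernoulli(\code{p[mu]}); and
#' neuronal activity \code{s[i, k]} Bernoulli(\code{lambda_{t[i]}(omega[k,
#' t[i]])}).
#'
#' @param params an \code{\link{assembly_model}}.
#' @param N number of neurons.
#' @param M number of time frames.
#' @param seed optional integer seed for reproducibility.
#' @param equal_sizes if \code{TRUE}, assign memberships in (nearly) equal
#'   blocks of size N/A instead of sampling them, as in benchmark figures
#'   where assemblies have identical sizes.
#' @return A list of class \code{assembly_sim} with elements \code{s} (N x M
#'   integer matrix), \code{t} (length-N membership vector), \code{omega}
#'   (M x A matrix) and \code{params}.
#' @examples
#' mod <- assembly_model(rep(1, 5), p = 0.1, lambda0 = 0.08, lambda1 = 0.6)
#' sim <- simulate_assemblies(mod, N = 50, M = 100, seed = 1)
#' dim(sim$s)
#' @export
simulate_assemblies <- function(params, N, M, seed = NULL, equal_sizes = FALSE) {
  stopifnot(inherits(params, "assembly_model"), N >= 1, M >= 1)
  if (!is.null(seed)) set.seed(seed)
  A <- params$A
  if (equal_sizes) {
    t <- sort(rep_len(seq_len(A), N))
  } else {
    t <- sample.int(A, N, replace = TRUE, prob = params$n)
  }
  omega <- matrix(stats::rbinom(M * A, 1L, rep(params$p, each = M)), M, A)
  lam <- ifelse(omega[, t, drop = FALSE] == 1L,
                rep(params$lambda1[t], each = M),
                rep(params$lambda0[t], each = M))  # M x N
  s <- matrix(stats::rbinom(M * N, 1L, lam), M, N)
  structure(list(s = t(s), t = t, omega = omega, params = params),
            class = "assembly_sim")
}
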