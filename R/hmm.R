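#' Parameters of the transient-detection hidden Markov model
#'
#' The trace model decomposes a recorded time series into an onset indicator
#' \code{s} (Bernoulli with rate \code{q} per second), a transient level
#' \code{c} that decays exponentially at rate \code{decay} between onsets and
#' jumps by a Gaussian innovation of scale \code{sigma_C} at an onset, a
#' baseline \code{b} performing a Gaussian random walk of scale
#' \code{sigma_B * sqrt(dt)} per step, and Gaussian observation noise of scale
#' \code{sigma_x}.
#'
#' @param q onset rate per second (q * dt must be < 1).
#' @param decay transient decay constant per second.
#' @param sigma_x observation noise scale (per step).
#' @param sigma_B baseline random-walk scale (per sqrt(second)).
#' @param sigma_C transient innovation scale (per step).
#' @return An object of class \code{trace_params}.
#' @export
trace_params <- function(q = 0.01, decay = 1.0, sigma_x = 1, sigma_B = 0.1,
                         sigma_C = 1) {
  v <- c(q = q, decay = decay, sigma_x = sigma_x, sigma_B = sigma_B,
         sigma_C = sigma_C)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all trace-model parameters must be finite and positive")
  structure(as.list(v), class = "trace_params")
}

#' Data-driven initial trace-model parameters
#'
#' Robust starting values for the plug-in refinement: the observation noise
#' scale from the median absolute deviation of first differences (scaled for
#' Gaussian consistency and the sqrt(2) inflation of differencing), a small
#' baseline scale relative to it, and a transient scale matched to the trace's
#' dynamic range.
#'
#' @param x numeric trace.
#' @param dt sampling interval in seconds.
#' @param q,decay initial onset rate and decay constant (per second).
#' @return A \code{trace_params} object.
#' @export
default_trace_params <- function(x, dt, q = 0.01, decay = 1.0) {
  if (any(!is.finite(x))) stop("trace contains non-finite values")
  sx <- 1.4826 * stats::mad(diff(x), constant = 1) / sqrt(2)
  if (sx <= 0) sx <- stats::sd(x)
  if (!is.finite(sx) || sx <= 0) sx <- 1e-3
  sC <- max(diff(range(x)) / 2, sx)
  trace_params(q = q, decay = decay, sigma_x = sx, sigma_B = sx / 10,
               sigma_C = sC)
}

#' One step of the per-step maximum-likelihood decision rule
#'
#' Given the decomposition at the previous frame and the new observation,
#' computes the closed-form conditional maximizers of transient and baseline
#' under both hypotheses (no onset: the transient decays deterministically and
#' the baseline absorbs the residual in proportion to the noise scales; onset:
#' the transient absorbs most of the residual) and picks the onset state by
#' comparing the prior-weighted maximized densities. Ties resolve to no onset.
#'
#' @param prev list with elements \code{s}, \code{c}, \code{b} at frame k-1.
#' @param x_k observation at frame k.
#' @param params a \code{\link{trace_params}}.
#' @param dt sampling interval in seconds.
#' @return A list with \code{s}, \code{c}, \code{b} at frame k.
#' @export
hmm_step <- function(prev, x_k, params, dt) {
  stopifnot(inherits(params, "trace_params"), params$q * dt < 1)
  vx <- params$sigma_x^2
  vB <- params$sigma_B^2 * dt
  vC <- params$sigma_C^2
  cstar <- prev$c * exp(-params$decay * dt)
  r <- x_k - cstar - prev$b
  b0 <- ((x_k - cstar) / vx + prev$b / vB) / (1 / vx + 1 / vB)
  lg0 <- -0.5 * (x_k - cstar - b0)^2 / vx - 0.5 * (b0 - prev$b)^2 / vB
  c1 <- cstar + r / (1 + vB / vC + vx / vC)
  b1 <- prev$b + (vB / vC) * (c1 - cstar)
  lg1 <- -0.5 * log(2 * pi * vC) - 0.5 * (x_k - c1 - b1)^2 / vx -
    0.5 * (b1 - prev$b)^2 / vB - 0.5 * (c1 - cstar)^2 / vC
  if (log(params$q * dt) + lg1 > log1p(-params$q * dt) + lg0)
    list(s = 1L, c = c1, b = b1)
  else
    list(s = 0L, c = cstar, b = b0)
}

#' Decompose a trace into onsets, transient and baseline
#'
#' Applies the per-step maximum-likelihood rule sequentially from the initial
#' condition \code{b[1] = x[1]}, \code{c[1] = 0}, \code{s[1] = 0}. The result
#' is a deterministic function of the trace and parameters. Wherever
#' \code{s[k] = 0}, the transient satisfies the exact decay identity
#' \code{c[k] = c[k-1] * exp(-decay * dt)}.
#'
#' @param x numeric trace (length >= 2, finite).
#' @param params a \code{\link{trace_params}}.
#' @param dt sampling interval in seconds.
#' @return A list of class \code{trace_decomposition} with integer vector
#'   \code{s} and numeric vectors \code{c} and \code{b}, all the length of
#'   \code{x}.
#' @export
decompose_trace <- function(x, params, dt) {
  stopifnot(inherits(params, "trace_params"), dt > 0, params$q * dt < 1)
  if (length(x) < 2L) stop("trace must have length >= 2")
  if (any(!is.finite(x))) stop("trace contains non-finite values")
  out <- .hmm_decompose(as.numeric(x), dt, params$q, params$decay,
                        params$sigma_x, params$sigma_B, params$sigma_C)
  structure(out, class = "trace_decomposition")
}

#' Plug-in refinement of trace-model parameters
#'
#' Alternates trace decomposition with moment re-estimates of the noise scales
#' and onset rate: the baseline-walk variance from mean squared baseline
#' increments over \code{dt}, the transient innovation variance from the mean
#' squared jumps at detected onsets, the observation variance from the mean
#' squared residual, and the onset rate from the detected onset count over the
#' recording duration. Two rounds are the default. Each scale is floored at
#' \code{eps} to guard against the singular collapse that further iterations
#' of the plug-in scheme can produce, and the transient scale is additionally
#' floored at the re-estimated observation noise scale: a variance taken from
#' one or two spurious noise-sized detections would otherwise collapse and
#' flood the next round with onsets (a transient below the noise floor is
#' undetectable in any case). For the same reason the transient variance is
#' only re-estimated when at least five onsets were detected; otherwise the
#' previous value is kept. When no onsets are detected the rate is floored at
#' one event per recording and flagged.
#'
#' @param x numeric trace.
#' @param params0 initial \code{\link{trace_params}} (default
#'   \code{\link{default_trace_params}}).
#' @param dt sampling interval in seconds.
#' @param n_rounds number of decompose/re-estimate rounds (>= 1).
#' @param eps lower floor on the sigma scales.
#' @return A list with elements \code{params} (refined \code{trace_params}),
#'   \code{decomposition} (at the refined parameters), and \code{flagged}
#'   (TRUE if the no-onset floor was applied).
#' @export
refine_params <- function(x, params0 = NULL, dt, n_rounds = 2L, eps = 1e-6) {
  if (n_rounds < 1L) stop("'n_rounds' must be >= 1")
  if (is.null(params0)) params0 <- default_trace_params(x, dt)
  stopifnot(inherits(params0, "trace_params"))
  M <- length(x) - 1L
  par <- params0
  flagged <- FALSE
  dec <- decompose_trace(x, par, dt)
  for (round in seq_len(n_rounds)) {
    cstar <- dec$c[-length(dec$c)] * exp(-par$decay * dt)
    db <- diff(dec$b)
    sB2 <- sum(db^2) / (M * dt)
    on <- which(dec$s[-1L] == 1L)               # onsets at frames 2..M+1
    M1 <- length(on)
    # a variance from a handful of (possibly spurious) jumps is meaningless
    # and collapses the next round; re-estimate only with enough onsets
    sC2 <- if (M1 >= 5L) sum((dec$c[on + 1L] - cstar[on])^2) / M1
           else par$sigma_C^2
    sx2 <- sum((x - dec$c - dec$b)^2) / M
    q <- M1 / (M * dt)
    if (M1 == 0L) { q <- 1 / (M * dt); flagged <- TRUE }
    sx <- max(sqrt(sx2), eps)
    par <- trace_params(q = min(q, 0.99 / dt), decay = par$decay,
                        sigma_x = sx,
                        sigma_B = max(sqrt(sB2), eps),
                        sigma_C = max(sqrt(sC2), sx, eps))
    dec <- decompose_trace(x, par, dt)
  }
  list(params = par, decomposition = dec, flagged = flagged)
}

#' Simulate a trace from the transient model
#'
#' Forward simulation of the onset/transient/baseline model; used by the
#' recovery benchmarks and for end-to-end tests that push simulated assembly
#' activity through a fluorescence model before binarization.
#'
#' @param M number of steps after the initial frame (trace length is M + 1).
#' @param params a \code{\link{trace_params}}.
#' @param dt sampling interval in seconds.
#' @param seed optional integer seed.
#' @param s optional 0/1 onset vector of length M + 1 to impose (e.g. assembly
#'   activity); when supplied the Bernoulli draw is skipped.
#' @param b0 initial baseline level.
#' @return A list with the observed trace \code{x} and the latent \code{s},
#'   \code{c}, \code{b}.
#' @export
simulate_trace <- function(M, params, dt, seed = NULL, s = NULL, b0 = 0) {
  stopifnot(inherits(params, "trace_params"), M >= 1, params$q * dt < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- M + 1L
  if (is.null(s)) s <- c(0L, stats::rbinom(M, 1L, params$q * dt))
  stopifnot(length(s) == n)
  cc <- numeric(n); b <- numeric(n)
  b[1] <- b0
  dec <- exp(-params$decay * dt)
  for (k in 2:n) {
    cstar <- cc[k - 1] * dec
    cc[k] <- if (s[k] == 1L) stats::rnorm(1, cstar, params$sigma_C) else cstar
    b[k] <- stats::rnorm(1, b[k - 1], params$sigma_B * sqrt(dt))
  }
  x <- stats::rnorm(n, b + cc, params$sigma_x)
  list(x = x, s = as.integer(s), c = cc, b = b)
}

#' Binarize a population of traces into an activity matrix
#'
#' Runs the per-trace plug-in refinement and decomposition for every neuron
#' and assembles the onset indicators into the binary neuron x frame matrix
#' used by the assembly samplers. The onset indicator is reported exactly as
#' the trace model defines it (no event dilation).
#'
#' @param traces numeric matrix with one column per neuron (rows = frames), or
#'   a list of equal-length numeric vectors.
#' @param dt sampling interval in seconds.
#' @param params0 optional shared initial \code{\link{trace_params}}; default
#'   is per-trace data-driven initialization.
#' @param n_rounds refinement rounds per trace.
#' @return A list with \code{s} (binary N x (frames) matrix, the first frame
#'   dropped since the model fixes \code{s[1] = 0}), and \code{params} (a data
#'   frame of refined per-neuron parameters).
#' @export
binarize_population <- function(traces, dt, params0 = NULL, n_rounds = 2L) {
  if (is.list(traces) && !is.data.frame(traces)) {
    len <- vapply(traces, length, integer(1))
    if (length(unique(len)) != 1L) stop("all traces must have equal length")
    traces <- do.call(cbind, traces)
  }
  traces <- as.matrix(traces)
  N <- ncol(traces)
  s <- matrix(0L, N, nrow(traces) - 1L)
  rows <- vector("list", N)
  for (j in seq_len(N)) {
    fit <- refine_params(traces[, j], params0 = params0, dt = dt,
                         n_rounds = n_rounds)
    s[j, ] <- fit$decomposition$s[-1L]
    rows[[j]] <- data.frame(neuron = j, q = fit$params$q,
                            sigma_x = fit$params$sigma_x,
                            sigma_B = fit$params$sigma_B,
                            sigma_C = fit$params$sigma_C,
                            flagged = fit$flagged)
  }
  list(s = s, params = do.call(rbind, rows))
}

#' Bin spike times into counts
#'
#' Converts a (neuron id, spike time) table into a neuron x bin count matrix
#' at a fixed bin width, the front-end used for electrophysiology recordings
#' before transient detection (default 0.6 s bins).
#'
#' @param spikes data frame with columns \code{neuron_id} and \code{time_s}.
#' @param bin bin width in seconds.
#' @param t_max optional recording end time (default the last spike).
#' @return A list with the count matrix \code{counts} (neurons x bins, rows
#'   named by neuron id) and the bin width \code{dt}.
#' @export
bin_spikes <- function(spikes, bin = 0.6, t_max = NULL) {
  stopifnot(all(c("neuron_id", "time_s") %in% names(spikes)))
  if (is.null(t_max)) t_max <- max(spikes$time_s)
  breaks <- seq(0, t_max + bin, by = bin)
  ids <- sort(unique(spikes$neuron_id))
  counts <- t(vapply(ids, function(id) {
    tabulate(findInterval(spikes$time_s[spikes$neuron_id == id],
                          breaks, left.open = TRUE, rightmost.closed = TRUE),
             nbins = length(breaks) - 1L)
  }, integer(length(breaks) - 1L)))
  rownames(counts) <- ids
  list(counts = counts, dt = bin)
}
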