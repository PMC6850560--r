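#' Select synchrony frames before inference
#'
#' Keeps the frames whose number of simultaneously active neurons is strictly
#' greater than a threshold. When \code{min_active} is not given it is derived
#' from a shuffle null: each neuron's activity is circularly shifted by an
#' independent random offset, destroying synchrony but preserving per-neuron
#' rates, and the threshold is the smallest count whose exceedance probability
#' under the null is below \code{null_p}.
#'
#' @param s N x M binary activity matrix.
#' @param min_active integer threshold on active cells per frame; frames with
#'   count > min_active are kept. NULL to derive from the shuffle null.
#' @param null_p significance level for the derived threshold.
#' @param n_shuffles number of circular-shift shuffles for the null.
#' @param seed optional seed for the shuffles.
#' @return A list with \code{s} (the filtered matrix), \code{kept}
#'   (original indices of the kept frames) and \code{min_active} (the
#'   threshold used).
#' @export
filter_frames <- function(s, min_active = NULL, null_p = 0.02,
                          n_shuffles = 200L, seed = NULL) {
  s <- check_binary_matrix(s)
  N <- nrow(s); M <- ncol(s)
  if (is.null(min_active)) {
    stopifnot(null_p > 0, null_p < 1, n_shuffles >= 1)
    if (!is.null(seed)) set.seed(seed)
    maxc <- N
    tail_counts <- numeric(maxc + 1L)            # tail_counts[m+1] ~ #frames with count > m
    total <- 0
    for (b in seq_len(n_shuffles)) {
      sh <- s
      off <- sample.int(M, N, replace = TRUE) - 1L
      for (i in seq_len(N)) if (off[i] > 0L)
        sh[i, ] <- sh[i, c((M - off[i] + 1L):M, 1L:(M - off[i]))]
      cc <- colSums(sh)
      tb <- tabulate(cc + 1L, nbins = maxc + 1L)
      tail_counts <- tail_counts + rev(cumsum(rev(tb)))
      total <- total + M
    }
    # exceedance P(count > m) = P(count >= m + 1)
    exceed <- c(tail_counts[-1L], 0) / total
    min_active <- (which(exceed < null_p)[1L]) - 1L
    if (is.na(min_active)) min_active <- maxc
  }
  if (min_active < 0) stop("'min_active' must be >= 0")
  keep <- which(colSums(s) > min_active)
  if (length(keep) == 0L)
    stop("no frames survive the activity filter (threshold ", min_active, ")")
  list(s = s[, keep, drop = FALSE], kept = keep, min_active = as.integer(min_active))
}

#' Select assemblies by their posterior features
#'
#' Applies the four feature filters used to isolate coherent assemblies:
#' activity strictly larger than \code{min_activity}, size strictly larger
#' than \code{min_size} neurons, synchrony strictly larger than
#' \code{min_synchrony} and asynchrony strictly lower than
#' \code{max_asynchrony}. Every assembly receives an audit row stating which
#' filters it failed.
#'
#' @param summaries data frame as returned by \code{\link{assembly_summary}}
#'   (columns \code{assembly}, \code{G}, \code{p}, \code{lambda0},
#'   \code{lambda1}).
#' @param min_activity minimum assembly activation probability (default 0.005,
#'   about one event per minute at typical volumetric imaging rates).
#' @param min_size minimum number of member neurons (default 5).
#' @param min_synchrony minimum synchrony lambda(1) (default 0.05).
#' @param max_asynchrony maximum asynchrony lambda(0) (default 0.05).
#' @return A list with \code{kept} (assembly labels passing all filters) and
#'   \code{audit} (one row per assembly with the filter outcomes and a
#'   rejection reason string).
#' @export
select_assemblies <- function(summaries, min_activity = 0.005, min_size = 5,
                              min_synchrony = 0.05, max_asynchrony = 0.05) {
  need <- c("assembly", "G", "p", "lambda0", "lambda1")
  stopifnot(all(need %in% names(summaries)))
  ok_act <- summaries$p > min_activity
  ok_size <- summaries$G > min_size
  ok_syn <- summaries$lambda1 > min_synchrony
  ok_asyn <- summaries$lambda0 < max_asynchrony
  keep <- ok_act & ok_size & ok_syn & ok_asyn
  reason <- vapply(seq_len(nrow(summaries)), function(i) {
    fails <- c(if (!ok_act[i]) "activity", if (!ok_size[i]) "size",
               if (!ok_syn[i]) "synchrony", if (!ok_asyn[i]) "asynchrony")
    if (length(fails) == 0L) "" else paste(fails, collapse = ";")
  }, character(1))
  audit <- data.frame(assembly = summaries$assembly, G = summaries$G,
                      p = summaries$p, lambda0 = summaries$lambda0,
                      lambda1 = summaries$lambda1, kept = keep,
                      rejected_on = reason)
  list(kept = summaries$assembly[keep], audit = audit)
}

#' Partition neurons into confidently assigned and free neurons
#'
#' A neuron is assigned when its modal aligned assembly reaches the stated
#' posterior confidence and that assembly survived feature selection; all
#' other neurons are free.
#'
#' @param membership data frame from \code{\link{membership_posterior}}.
#' @param confidence required posterior membership frequency (default 0.99).
#' @param kept_assemblies optional vector of assembly labels that passed
#'   \code{\link{select_assemblies}}; default keeps all.
#' @return The membership data frame with an added logical column
#'   \code{assigned}; free neurons have \code{assigned = FALSE}.
#' @export
free_neurons <- function(membership, confidence = 0.99, kept_assemblies = NULL) {
  stopifnot(all(c("neuron", "assembly", "confidence") %in% names(membership)))
  assigned <- membership$confidence >= confidence
  if (!is.null(kept_assemblies))
    assigned <- assigned & membership$assembly %in% kept_assemblies
  membership$assigned <- assigned
  membership
}
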