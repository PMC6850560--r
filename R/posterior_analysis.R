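#' Assembly time-correlation graph with posterior-confidence edges
#'
#' Builds the assembly interaction graph from posterior samples of the
#' assembly-state matrix: for every saved sample the Pearson correlation
#' between all pairs of (aligned) assembly state columns is computed, and an
#' edge is added between two assemblies when their correlation is positive in
#' at least \code{edge_confidence} of the samples. Edge weights are the mean
#' correlation across samples. Pairs with a constant state column in a sample
#' have undefined correlation there and that sample is skipped for the pair.
#'
#' @param trace an \code{assembly_trace} run with \code{record_omega = TRUE}.
#' @param edge_confidence required fraction of posterior samples with positive
#'   correlation (default 0.95).
#' @param keep optional vector of aligned assembly labels to include (e.g. the
#'   survivors of \code{\link{select_assemblies}}).
#' @param alignment optional result of \code{\link{align_trace}}.
#' @param min_samples minimum number of post-burn-in samples required.
#' @return An \code{igraph} undirected graph whose vertices are assembly
#'   labels, with edge attribute \code{weight} (mean correlation) and
#'   \code{support} (fraction of samples with positive correlation).
#' @export
correlation_graph <- function(trace, edge_confidence = 0.95, keep = NULL,
                              alignment = NULL, min_samples = 20L) {
  stopifnot(inherits(trace, "assembly_trace"))
  if (length(trace$omega_samples) < min_samples)
    stop("need at least ", min_samples, " posterior samples of omega")
  if (is.null(alignment)) alignment <- align_trace(trace)
  labs <- if (is.null(keep)) sort(unique(alignment$reference)) else sort(keep)
  if (length(labs) < 2L) stop("need at least two assemblies to build a graph")
  nlab <- length(labs)
  pos <- tot <- wsum <- matrix(0, nlab, nlab)
  for (r in seq_along(trace$omega_samples)) {
    om <- trace$omega_samples[[r]]
    ids <- attr(om, "assembly_id")
    lab <- alignment$maps[[r]][as.character(ids)]
    idx <- match(labs, lab)
    present <- which(!is.na(idx))
    if (length(present) < 2L) next
    sub <- canon_omega(om[, idx[present], drop = FALSE])
    sdv <- apply(sub, 2L, stats::sd)
    cors <- suppressWarnings(stats::cor(sub))
    for (a in seq_along(present)) for (b in seq_along(present)) {
      if (b <= a) next
      if (sdv[a] == 0 || sdv[b] == 0) next      # undefined correlation, skip
      ia <- present[a]; ib <- present[b]
      tot[ia, ib] <- tot[ia, ib] + 1
      wsum[ia, ib] <- wsum[ia, ib] + cors[a, b]
      if (cors[a, b] > 0) pos[ia, ib] <- pos[ia, ib] + 1
    }
  }
  edges <- which(tot > 0 & pos / pmax(tot, 1) >= edge_confidence, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nlab, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(labs))
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges),
                           weight = wsum[edges] / tot[edges],
                           support = pos[edges] / tot[edges])
  }
  g
}

#' Community structure of an assembly graph
#'
#' Edge-betweenness (Girvan-Newman) community detection on the assembly
#' correlation graph, identifying subnetworks of temporally co-active
#' assemblies.
#'
#' @param graph an igraph graph, e.g. from \code{\link{correlation_graph}}.
#' @return A data frame with columns \code{assembly} and \code{community}.
#' @export
assembly_communities <- function(graph) {
  stopifnot(igraph::vcount(graph) > 0)
  cl <- igraph::cluster_edge_betweenness(graph, weights = NULL)
  data.frame(assembly = igraph::V(graph)$name,
             community = as.integer(igraph::membership(cl)))
}

#' Spatial extension of assemblies
#'
#' For each assembly, the area of the ellipse fitting the 2D distribution of
#' its member neurons: \eqn{E = \pi \sqrt{\xi_1 \xi_2}} where the \eqn{\xi}
#' are the eigenvalues of the XY coordinate covariance within the assembly.
#' A compactness null is reported as the percentile of E among size-matched
#' random neuron groups.
#'
#' @param membership data frame with columns \code{neuron} and \code{assembly}
#'   (e.g. from \code{\link{membership_posterior}}, optionally filtered to
#'   assigned neurons).
#' @param coords data frame with columns \code{id}, \code{x}, \code{y}
#'   (\code{z} ignored if present) covering the assigned neurons.
#' @param n_null random size-matched groups per assembly (0 to skip the null).
#' @param seed optional seed for the resampling null.
#' @return A data frame per assembly: \code{size}, \code{E} (NA and flagged if
#'   fewer than 3 located members), null mean and percentile of E.
#' @export
spatial_summary <- function(membership, coords, n_null = 1000L, seed = NULL) {
  stopifnot(all(c("neuron", "assembly") %in% names(membership)),
            all(c("id", "x", "y") %in% names(coords)))
  if (!is.null(seed)) set.seed(seed)
  loc <- match(membership$neuron, coords$id)
  if (anyNA(loc)) stop("coordinates must cover all assigned neurons")
  xy <- as.matrix(coords[loc, c("x", "y")])
  ext <- function(idx) {
    if (length(idx) < 3L) return(NA_real_)
    ev <- eigen(stats::cov(xy[idx, , drop = FALSE]), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
    pi * sqrt(ev[1] * ev[2])
  }
  labs <- sort(unique(membership$assembly))
  rows <- lapply(labs, function(a) {
    idx <- which(membership$assembly == a)
    E <- ext(idx)
    null_mean <- NA_real_; pct <- NA_real_
    if (!is.na(E) && n_null > 0) {
      nullE <- replicate(n_null, ext(sample.int(nrow(xy), length(idx))))
      null_mean <- mean(nullE, na.rm = TRUE)
      pct <- mean(nullE <= E, na.rm = TRUE)
    }
    data.frame(assembly = a, size = length(idx), E = E,
               null_mean_E = null_mean, null_percentile = pct,
               flagged = is.na(E))
  })
  do.call(rbind, rows)
}

#' Correlate assembly activity with an external regressor
#'
#' For each posterior sample, computes the Pearson correlation between each
#' (aligned) assembly's state column and an external covariate sampled at the
#' same frames (running speed, pupil area, wheel velocity, ...), summarizing
#' the posterior distribution of the correlation per assembly.
#'
#' @param trace an \code{assembly_trace} run with \code{record_omega = TRUE}.
#' @param regressor numeric vector of length M.
#' @param alignment optional result of \code{\link{align_trace}}.
#' @return A data frame per assembly with the posterior mean, SD and central
#'   95\% interval of the correlation.
#' @export
regressor_correlation <- function(trace, regressor, alignment = NULL) {
  stopifnot(inherits(trace, "assembly_trace"), length(regressor) == trace$M)
  if (length(trace$omega_samples) == 0L)
    stop("trace was run with record_omega = FALSE")
  if (is.null(alignment)) alignment <- align_trace(trace)
  acc <- list()
  for (r in seq_along(trace$omega_samples)) {
    om <- trace$omega_samples[[r]]
    ids <- attr(om, "assembly_id")
    lab <- alignment$maps[[r]][as.character(ids)]
    om <- canon_omega(om)
    sdv <- apply(om, 2L, stats::sd)
    ok <- sdv > 0
    if (!any(ok)) next
    cr <- suppressWarnings(stats::cor(om[, ok, drop = FALSE], regressor))
    acc[[length(acc) + 1L]] <- data.frame(assembly = lab[ok], r = as.vector(cr))
  }
  all <- do.call(rbind, acc)
  labs <- sort(unique(all$assembly))
  do.call(rbind, lapply(labs, function(a) {
    v <- all$r[all$assembly == a]
    data.frame(assembly = a, mean = mean(v), sd = stats::sd(v),
               q025 = stats::quantile(v, 0.025, names = FALSE),
               q975 = stats::quantile(v, 0.975, names = FALSE),
               n_samples = length(v))
  }))
}

#' Write an assembly graph to disk
#'
#' Writes the correlation graph as an edge-list CSV (columns: from, to,
#' weight, support) or as GraphML.
#'
#' @param graph an igraph graph from \code{\link{correlation_graph}}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"graphml"}.
#' @return The path, invisibly.
#' @export
write_assembly_graph <- function(graph, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    d <- data.frame(from = el[, 1], to = el[, 2])
    for (a in igraph::edge_attr_names(graph))
      d[[a]] <- igraph::edge_attr(graph, a)
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
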