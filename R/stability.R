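# Network topology, natural-connectivity robustness, and MCC hub ranking.

# coerce a cooccurrence_network / igraph / edge tibble to igraph
as_network_graph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  if (inherits(net, "cooccurrence_network")) {
    return(igraph::graph_from_data_frame(
      net$edges[, c("from", "to", setdiff(names(net$edges), c("from", "to")))],
      directed = FALSE, vertices = net$nodes))
  }
  if (is.data.frame(net)) {
    return(igraph::graph_from_data_frame(net, directed = FALSE))
  }
  abort("cannot interpret network input", class = "gutstab_bad_network")
}

#' Natural connectivity of a network
#'
#' `ln((1/N) sum_i e^{k_i})` where `k_i` are the eigenvalues of the
#' unweighted 0/1 adjacency matrix: the log of the mean Estrada index
#' contribution, a redundancy-of-closed-walks measure of robustness.
#' Computed via log-sum-exp for numerical stability. An edgeless graph of
#' any size scores exactly 0.
#'
#' @param net `cooccurrence_network`, igraph, or edge data frame.
#' @param weighted use |r|-weighted adjacency instead of 0/1 (off by
#'   default; the usual formulation is unweighted).
#' @return non-negative real.
#' @export
natural_connectivity <- function(net, weighted = FALSE) {
  g <- as_network_graph(net)
  n <- igraph::vcount(g)
  if (n == 0) abort("empty node set", class = "gutstab_bad_network")
  A <- igraph::as_adjacency_matrix(
    g, sparse = FALSE,
    attr = if (weighted && "r" %in% igraph::edge_attr_names(g)) "r" else NULL)
  if (!weighted) A <- (A != 0) * 1
  if (weighted) A <- abs(A)
  k <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  m <- max(k)
  m + log(sum(exp(k - m))) - log(n)
}

#' Topological property summary of a network
#'
#' The standard co-occurrence network property bundle: node and edge
#' counts, average neighbours `2E/N`, characteristic path length (mean
#' unweighted shortest path over connected ordered pairs only — the usual
#' network-analyzer convention for disconnected graphs), mean local
#' clustering coefficient (degree < 2 counted as 0, or excluded via
#' `isolate_clustering = "exclude"`), density `2E/(N(N-1))`, degree
#' heterogeneity `sd_pop(degree)/mean(degree)`, and degree centralization
#' `(N/(N-2)) (max_deg/(N-1) - density)`.
#'
#' @param net network input (see [natural_connectivity()]).
#' @param isolate_clustering `"zero"` (default) counts degree<2 nodes as 0
#'   in the mean clustering; `"exclude"` drops them.
#' @return one-row tibble of the eight metrics.
#' @export
topology_summary <- function(net, isolate_clustering = c("zero", "exclude")) {
  isolate_clustering <- match.arg(isolate_clustering)
  g <- as_network_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) abort("need at least 2 nodes", class = "gutstab_bad_network")
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  dmat <- igraph::distances(g, weights = NA)
  finite <- dmat[is.finite(dmat) & dmat > 0]
  cpl <- if (length(finite)) mean(finite) else NA_real_
  loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  clust <- if (isolate_clustering == "zero") mean(loc) else {
    if (any(deg >= 2)) mean(loc[deg >= 2]) else NA_real_
  }
  dens <- 2 * e / (n * (n - 1))
  mdeg <- mean(deg)
  het <- if (mdeg > 0) sqrt(mean((deg - mdeg)^2)) / mdeg else 0
  centr <- if (n > 2) (n / (n - 2)) * (max(deg) / (n - 1) - dens) else NA_real_
  tibble::tibble(
    n_nodes = n, n_edges = e, avg_neighbors = 2 * e / n,
    characteristic_path_length = cpl, clustering_coefficient = clust,
    density = dens, heterogeneity = het, centralization = centr
  )
}

#' Natural-connectivity robustness curve under node removal
#'
#' For each removal fraction on the grid, removes that share of nodes —
#' uniformly at random (averaged over `n_reps` draws) or in descending
#' degree order (deterministic) — and records the natural connectivity of
#' the induced subgraph on the survivors.
#'
#' @param net network input with at least 3 nodes.
#' @param strategy `"random"` or `"degree"` (targeted attack).
#' @param max_fraction largest removal fraction, `< 1`.
#' @param step grid step.
#' @param n_reps random-removal replicates per fraction.
#' @param seed integer seed.
#' @return `robustness_curve` object; its tibble has `fraction`,
#'   `n_removed`, `mean_nc`, `sd_nc`.
#' @export
robustness_curve <- function(net, strategy = c("random", "degree"),
                             max_fraction = 0.8, step = 0.05,
                             n_reps = 100, seed = 1L) {
  strategy <- match.arg(strategy)
  if (max_fraction >= 1) abort("max_fraction must be < 1",
                               class = "gutstab_bad_config")
  g <- as_network_graph(net)
  n <- igraph::vcount(g)
  if (n < 3) abort("need at least 3 nodes", class = "gutstab_bad_network")
  fractions <- seq(0, max_fraction, by = step)
  deg_order <- order(igraph::degree(g), decreasing = TRUE)
  set.seed(child_seed(seed, "removal"))
  rows <- purrr::map_dfr(fractions, function(f) {
    n_rm <- round(f * n)
    if (n_rm >= n) n_rm <- n - 1
    if (strategy == "degree") {
      keep <- setdiff(seq_len(n), deg_order[seq_len(n_rm)])
      nc <- natural_connectivity(igraph::induced_subgraph(g, keep))
      tibble::tibble(fraction = f, n_removed = n_rm, mean_nc = nc, sd_nc = 0)
    } else {
      ncs <- vapply(seq_len(n_reps), function(r) {
        keep <- if (n_rm == 0) seq_len(n) else
          setdiff(seq_len(n), sample(n, n_rm))
        natural_connectivity(igraph::induced_subgraph(g, keep))
      }, numeric(1))
      tibble::tibble(fraction = f, n_removed = n_rm,
                     mean_nc = mean(ncs), sd_nc = sd(ncs))
    }
  })
  structure(list(curve = rows, strategy = strategy, n_reps = n_reps,
                 seed = seed), class = "robustness_curve")
}

#' @export
tidy.robustness_curve <- function(x, ...) x$curve

#' @export
glance.robustness_curve <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy, n_reps = x$n_reps,
    nc_intact = x$curve$mean_nc[1],
    auc = sum(diff(x$curve$fraction) *
              (head(x$curve$mean_nc, -1) + x$curve$mean_nc[-1]) / 2)
  )
}

#' @export
autoplot.robustness_curve <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction, .data$mean_nc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_nc - .data$sd_nc,
                                      ymax = .data$mean_nc + .data$sd_nc),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Fraction of nodes removed",
                  y = "Natural connectivity",
                  title = paste0("Robustness (", object$strategy, " removal)")) +
    ggplot2::theme_minimal()
}

#' Maximal clique centrality (MCC) hub ranking
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`.
#' An edge that is itself a maximal clique contributes 1, so a node whose
#' neighbours are mutually non-adjacent scores exactly its degree, as in
#' the reference definition. Ranking is by descending score with
#' competition ranking for ties ("1, 2, 2, 4"), reported as `rank/N`.
#'
#' @param net network input.
#' @param clique_cap abort (rather than hang) if the maximal-clique count
#'   exceeds this.
#' @return `hub_ranking` tibble: `node`, `mcc`, `rank`, `n_nodes`,
#'   `rank_label`.
#' @export
mcc_scores <- function(net, clique_cap = 1e6) {
  g <- as_network_graph(net)
  n <- igraph::vcount(g)
  if (n < 1) abort("empty node set", class = "gutstab_bad_network")
  n_cl <- igraph::count_max_cliques(g, min = 2)
  if (n_cl > clique_cap) {
    abort(paste0("maximal clique count ", n_cl, " exceeds cap ", clique_cap),
          class = "gutstab_clique_cap")
  }
  score <- setNames(rep(0, n), igraph::V(g)$name %||% as.character(seq_len(n)))
  if (n_cl > 0) {
    for (cl in igraph::max_cliques(g, min = 2)) {
      w <- factorial(length(cl) - 1)
      score[as.integer(cl)] <- score[as.integer(cl)] + w
    }
  }
  out <- tibble::tibble(
    node = names(score), mcc = unname(score),
    rank = unname(rank(-score, ties.method = "min")),
    n_nodes = n
  )
  out$rank_label <- paste0(out$rank, "/", n)
  out <- dplyr::arrange(out, .data$rank, .data$node)
  class(out) <- c("hub_ranking", class(out))
  out
}
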