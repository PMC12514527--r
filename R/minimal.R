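#' Seed regions for the behaviour-linked minimal network
#'
#' Selects regions whose hub scores correlate positively and significantly
#' with late extinction-learning performance.
#'
#' @param correlations A [behavior_hub_correlation()] table.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of node names (possibly empty, with a warning).
#' @export
select_behavior_hubs <- function(correlations, alpha = 0.05) {
  stopifnot(all(c("node", "r", "p") %in% names(correlations)))
  keep <- !is.na(correlations$r) & correlations$r > 0 & correlations$p < alpha
  seeds <- correlations$node[keep]
  if (length(seeds) == 0)
    warning("no region passed the positive-correlation threshold")
  seeds
}

#' Extract the behaviour-seeded minimal network
#'
#' Members are the seeds plus every node adjacent to a seed in the source
#' network; the minimal network is the induced subgraph on the members (all
#' source edges among members, including neighbour-neighbour ones). Louvain
#' communities are computed on the result.
#'
#' @param source igraph network (e.g. the reactivation-group consensus
#'   network).
#' @param seeds Character vector of seed node names (non-empty, subset of the
#'   source's nodes).
#' @param seed Integer seed for the Louvain run.
#' @return List of class `minimal_network`: `graph` (induced subgraph),
#'   `seeds`, `members`, `partition`.
#' @export
extract_minimal_network <- function(source, seeds, seed = 1L) {
  nodes <- igraph::V(source)$name
  if (length(seeds) == 0) stop("empty seed set")
  bad <- setdiff(seeds, nodes)
  if (length(bad) > 0) stop("seeds not in source: ", paste(bad, collapse = ", "))
  nb <- unlist(lapply(seeds, function(s)
    igraph::V(source)$name[igraph::neighbors(source, s)]))
  members <- nodes[nodes %in% union(seeds, nb)] # source node order
  g <- igraph::induced_subgraph(source, members)
  structure(list(graph = g, seeds = seeds,
                 members = igraph::V(g)$name,
                 partition = detect_communities(g, seed = seed)),
            class = "minimal_network")
}

#' @export
print.minimal_network <- function(x, ...) {
  cat("<minimal_network>", length(x$members), "members (",
      length(x$seeds), "seeds ),", igraph::ecount(x$graph), "edges,",
      length(unique(x$partition$membership)), "communities\n")
  invisible(x)
}

#' Rank minimal-network members by hub score, closeness and betweenness
#'
#' Centralities are recomputed on the minimal network itself, and each is
#' ranked in descending order (rank 1 = highest; average ranks on ties).
#'
#' @param mn A [extract_minimal_network()] result (>= 2 members).
#' @return data.frame (node, hub_score, closeness, betweenness, rank_hub,
#'   rank_closeness, rank_betweenness).
#' @export
rank_minimal_centralities <- function(mn) {
  stopifnot(inherits(mn, "minimal_network"))
  if (length(mn$members) < 2) stop("need >= 2 members to rank")
  hs <- hub_scores(mn$graph)
  pc <- path_centralities(mn$graph)
  out <- data.frame(node = pc$node, hub_score = unname(hs[pc$node]),
                    closeness = pc$closeness, betweenness = pc$betweenness)
  out$rank_hub <- rank(-out$hub_score, ties.method = "average")
  out$rank_closeness <- rank(-out$closeness, ties.method = "average")
  out$rank_betweenness <- rank(-out$betweenness, ties.method = "average")
  out
}
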