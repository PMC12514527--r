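# Edge lengths for shortest-path metrics: strong correlation = short
# distance, so length = 1/weight.
.edge_lengths <- function(net) {
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(net))
  1 / w
}

#' Global efficiency
#'
#' Mean of the inverse shortest-path lengths over all unordered node pairs.
#' Distances use edge length 1/weight; disconnected pairs contribute 0.
#'
#' @param net igraph network (>= 2 nodes).
#' @return Numeric scalar.
#' @export
global_efficiency <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("need at least 2 nodes")
  d <- igraph::distances(net, weights = .edge_lengths(net))
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Global clustering coefficient (transitivity)
#'
#' 3 x triangles / connected triples on the binarized edge set.
#'
#' @param net igraph network (>= 3 nodes).
#' @return Numeric scalar; 0 when the graph has no connected triples.
#' @export
clustering_coefficient <- function(net) {
  if (igraph::vcount(net) < 3) stop("need at least 3 nodes")
  x <- igraph::transitivity(net, type = "global")
  if (is.nan(x)) 0 else x
}

#' Edge density
#'
#' @param net igraph network (>= 2 nodes).
#' @return |E| / (n(n-1)/2).
#' @export
edge_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("need at least 2 nodes")
  igraph::ecount(net) / (n * (n - 1) / 2)
}

# Leading eigenvector of a symmetric non-negative adjacency matrix,
# max-normalized to 1. Used by both the public hub_scores() and the
# permutation-test inner loop so observed and null values share one code
# path.
.hub_from_adjacency <- function(a) {
  if (all(a == 0)) return(rep(0, nrow(a)))
  v <- eigen(a, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  v[v < .Machine$double.eps^0.5 * max(v)] <- 0
  v / max(v)
}

#' Eigenvector-centrality hub scores
#'
#' Entries of the leading eigenvector of the weighted adjacency matrix,
#' scaled so the maximum is 1. On disconnected graphs the leading eigenpair
#' of the whole matrix is used, so the dominant component sets the scale and
#' isolated nodes score 0.
#'
#' @param net igraph network (non-empty).
#' @return Named numeric vector of hub scores in [0, 1].
#' @export
hub_scores <- function(net) {
  if (igraph::vcount(net) < 1) stop("empty graph")
  if (igraph::ecount(net) == 0) {
    warning("edgeless network: all hub scores are 0")
    return(stats::setNames(rep(0, igraph::vcount(net)),
                           igraph::V(net)$name))
  }
  a <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  stats::setNames(.hub_from_adjacency(a), igraph::V(net)$name)
}

#' Betweenness and closeness centrality
#'
#' Weighted shortest paths with edge length 1/weight. Betweenness uses
#' fractional counting over tied shortest paths (Brandes); closeness is
#' (k - 1) / sum of distances to the k - 1 other nodes of the node's own
#' connected component (0 for isolated nodes).
#'
#' @param net igraph network (non-empty).
#' @return data.frame (node, betweenness, closeness).
#' @export
path_centralities <- function(net) {
  if (igraph::vcount(net) < 1) stop("empty graph")
  len <- .edge_lengths(net)
  btw <- igraph::betweenness(net, weights = len, directed = FALSE)
  d <- igraph::distances(net, weights = len)
  clo <- apply(d, 1, function(row) {
    fin <- is.finite(row) & row > 0
    if (!any(fin)) 0 else sum(fin) / sum(row[fin])
  })
  data.frame(node = igraph::V(net)$name, betweenness = unname(btw),
             closeness = unname(clo))
}

#' Global metrics of one network
#'
#' @param net igraph network.
#' @return data.frame with global_efficiency, clustering_coefficient,
#'   edge_density.
#' @export
network_metrics <- function(net) {
  data.frame(global_efficiency = global_efficiency(net),
             clustering_coefficient = clustering_coefficient(net),
             edge_density = edge_density(net))
}

#' Express per-animal metric values as a percentage of the group baseline
#'
#' Each value is divided by the mean of its group's values in the baseline
#' bin and multiplied by 100, so every group's baseline-bin mean maps to
#' 100 %.
#'
#' @param df data.frame with columns animal_id, group, bin, value (extra
#'   columns pass through).
#' @param baseline_bin Baseline bin index (default 1).
#' @return The input with a `normalized` column added.
#' @export
normalize_to_baseline <- function(df, baseline_bin = 1L) {
  stopifnot(all(c("animal_id", "group", "bin", "value") %in% names(df)))
  if (!any(df$bin == baseline_bin)) stop("baseline bin absent from data")
  base <- tapply(df$value[df$bin == baseline_bin],
                 df$group[df$bin == baseline_bin], mean)
  if (any(base == 0))
    stop("zero baseline mean for group(s): ",
         paste(names(base)[base == 0], collapse = ", "))
  df$normalized <- as.numeric(100 * df$value / base[as.character(df$group)])
  df
}
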