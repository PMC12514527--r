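# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Louvain community detection
#'
#' Weighted-modularity maximisation (resolution 1), made reproducible by a
#' seeded run. An edgeless graph yields every node in its own community with
#' Q = 0.
#'
#' @param net igraph network.
#' @param seed Integer seed controlling the Louvain vertex ordering.
#' @return A list of class `community_partition`: `membership` (named integer
#'   vector), `modularity` (Q of the returned partition).
#' @export
detect_communities <- function(net, seed = 1L) {
  nodes <- igraph::V(net)$name
  if (igraph::ecount(net) == 0) {
    membership <- stats::setNames(seq_along(nodes), nodes)
    return(structure(list(membership = membership, modularity = 0),
                     class = "community_partition"))
  }
  cl <- .with_seed(seed, igraph::cluster_louvain(net, weights = igraph::E(net)$weight))
  membership <- stats::setNames(as.integer(igraph::membership(cl)), nodes)
  q <- igraph::modularity(net, membership, weights = igraph::E(net)$weight)
  structure(list(membership = membership, modularity = q),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition>", length(unique(x$membership)), "communities,",
      "Q =", format(x$modularity, digits = 4), "\n")
  invisible(x)
}

#' Shannon-entropy community diversity scores
#'
#' For each node, the distribution of its neighbors over communities is
#' computed and its Shannon entropy (base 2, bits) taken. Isolated nodes
#' score 0.
#'
#' @param net igraph network.
#' @param partition A [detect_communities()] result covering `net`'s nodes.
#' @return Named numeric vector of diversity scores (bits).
#' @export
diversity_scores <- function(net, partition) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(partition$membership)))
    stop("partition does not cover all nodes")
  memb <- partition$membership[nodes]
  vapply(seq_along(nodes), function(i) {
    nb <- igraph::neighbors(net, i)
    if (length(nb) == 0) return(0)
    p <- table(memb[as.integer(nb)]) / length(nb)
    -sum(p * log2(p))
  }, numeric(1)) -> h
  stats::setNames(h, nodes)
}

#' Classify nodes into the connector/provincial hub role taxonomy
#'
#' Nodes in the top `quantile` of hub scores are hubs; nodes in the top
#' `quantile` of diversity are connectors. Hubs that are also connectors are
#' Connector Hubs; hubs that are not are Provincial Hubs; non-hub connectors
#' are Non-Hub Connectors; the rest are Peripheral. Ties at the threshold are
#' included (>=).
#'
#' @param hub_scores Named numeric vector (see [hub_scores()]).
#' @param diversity Named numeric vector (see [diversity_scores()]), same
#'   nodes.
#' @param quantile Upper-quantile cut (default 0.20).
#' @return data.frame (node, hub_score, diversity, is_hub, is_connector,
#'   role) with role one of "ConnectorHub", "ProvincialHub",
#'   "NonHubConnector", "Peripheral".
#' @export
classify_node_roles <- function(hub_scores, diversity, quantile = 0.20) {
  if (!identical(sort(names(hub_scores)), sort(names(diversity))))
    stop("hub_scores and diversity must cover the same nodes")
  diversity <- diversity[names(hub_scores)]
  thr_h <- stats::quantile(hub_scores, 1 - quantile, names = FALSE)
  thr_d <- stats::quantile(diversity, 1 - quantile, names = FALSE)
  is_hub <- hub_scores >= thr_h
  is_conn <- diversity >= thr_d
  role <- ifelse(is_hub & is_conn, "ConnectorHub",
          ifelse(is_hub, "ProvincialHub",
          ifelse(is_conn, "NonHubConnector", "Peripheral")))
  data.frame(node = names(hub_scores), hub_score = unname(hub_scores),
             diversity = unname(diversity), is_hub = unname(is_hub),
             is_connector = unname(is_conn), role = unname(role))
}
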