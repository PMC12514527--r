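# Edge matrix + weights + node count; the permutation test's working
# representation of a network.
.edge_repr <- function(net) {
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  list(edges = el, weights = igraph::E(net)$weight, n = igraph::vcount(net))
}

.adj_from_repr <- function(r) {
  a <- matrix(0, r$n, r$n)
  a[r$edges] <- r$weights
  a[r$edges[, c(2, 1), drop = FALSE]] <- r$weights
  a
}

#' Degree-preserving rewiring of a weighted network
#'
#' Randomises topology by double-edge swaps that preserve every node's degree
#' exactly; each edge keeps its weight while its endpoints change. Swap count
#' defaults to 10 x |E| (a standard mixing heuristic).
#'
#' @param net igraph network with >= 2 edges.
#' @param nswap Number of successful swaps to perform (default 10 x |E|).
#' @return A rewired igraph network with the same node set, degree sequence
#'   and multiset of edge weights.
#' @export
rewire_network <- function(net, nswap = 10L * igraph::ecount(net)) {
  if (igraph::ecount(net) < 2) stop("network too sparse to rewire")
  r <- .edge_repr(net)
  e2 <- .rewire_edges_cpp(r$edges, as.integer(nswap), as.integer(100L * nswap))
  g <- igraph::make_empty_graph(n = r$n, directed = FALSE)
  igraph::V(g)$name <- igraph::V(net)$name
  g <- igraph::add_edges(g, t(e2))
  igraph::E(g)$weight <- r$weights
  g
}

#' BCa bootstrap confidence interval for a two-group mean difference
#'
#' Resamples each group with replacement `n_boot` times to form the bootstrap
#' distribution of mean(A) - mean(B), then computes bias-corrected and
#' accelerated intervals: the bias correction z0 comes from the fraction of
#' bootstrap draws below the observed difference, and the acceleration from
#' the jackknife skewness over the pooled observations. A level is starred
#' when its interval excludes zero.
#'
#' @param a,b Numeric vectors of per-animal values (>= 2 each).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param levels Confidence levels (default 0.95, 0.99, 0.999).
#' @param metric Label carried into the result.
#' @return A list of class `bootstrap_result`: observed, ci (data.frame
#'   level/lower/upper/excludes_zero), stars, n_boot, degenerate flag,
#'   boot (the bootstrap draws).
#' @export
bootstrap_group_difference <- function(a, b, n_boot = 1000L,
                                       levels = c(0.95, 0.99, 0.999),
                                       metric = "metric") {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  observed <- mean(a) - mean(b)
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(sample(a, replace = TRUE)) - mean(sample(b, replace = TRUE))
  }, numeric(1))
  degenerate <- stats::sd(boot) == 0

  if (degenerate) {
    ci <- data.frame(level = levels, lower = observed, upper = observed)
  } else {
    # bias correction (midrank handling of ties with the observed value)
    frac <- (sum(boot < observed) + 0.5 * sum(boot == observed)) / n_boot
    frac <- min(max(frac, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
    z0 <- stats::qnorm(frac)
    # acceleration from the jackknife over pooled observations
    jack <- c(vapply(seq_along(a), function(i) mean(a[-i]) - mean(b), numeric(1)),
              vapply(seq_along(b), function(i) mean(a) - mean(b[-i]), numeric(1)))
    dev <- mean(jack) - jack
    denom <- sum(dev^2)^1.5
    acc <- if (denom == 0) 0 else sum(dev^3) / (6 * denom)
    ci <- do.call(rbind, lapply(levels, function(lv) {
      zl <- stats::qnorm((1 - lv) / 2)
      zu <- -zl
      a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
      a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - acc * (z0 + zu)))
      q <- stats::quantile(boot, c(a1, a2), names = FALSE, type = 7)
      data.frame(level = lv, lower = q[1], upper = q[2])
    }))
  }
  ci$excludes_zero <- ci$lower > 0 | ci$upper < 0
  stars <- paste(rep("*", sum(ci$excludes_zero)), collapse = "")
  structure(list(metric = metric, observed = observed, ci = ci,
                 stars = stars, n_boot = n_boot, degenerate = degenerate,
                 boot = boot),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>", x$metric, " observed diff =",
      format(x$observed, digits = 4),
      if (nzchar(x$stars)) x$stars else "(n.s.)", "\n")
  print(x$ci, row.names = FALSE)
  invisible(x)
}

#' Rewiring permutation test on nodal hub-score differences
#'
#' The observed per-node difference in eigenvector-centrality hub score
#' between two networks (A minus B) is compared against a null built by
#' degree-preserving rewiring: each draw rewires both networks independently
#' (weights travelling with edges), recomputes hub scores and records the
#' null difference. Two-sided p-values use the proportion of null draws with
#' |null| >= |observed|, with +1 smoothing so p > 0.
#'
#' @param net_a,net_b igraph networks over the identical node set (e.g. the
#'   two group consensus networks).
#' @param n_perm Number of rewired draws (default 1000).
#' @param seed Integer seed.
#' @param nswap_factor Swaps per draw as a multiple of |E| (default 10).
#' @return A list of class `permutation_result`: `table` (data.frame node,
#'   observed, p), `null` (n_perm x n matrix), `n_perm`.
#' @export
rewire_permutation_test <- function(net_a, net_b, n_perm = 1000L, seed = 1L,
                                    nswap_factor = 10L) {
  nodes <- igraph::V(net_a)$name
  if (!identical(nodes, igraph::V(net_b)$name))
    stop("networks must share an identical node set")
  if (igraph::ecount(net_a) < 2 || igraph::ecount(net_b) < 2)
    stop("network too sparse to rewire")
  ra <- .edge_repr(net_a)
  rb <- .edge_repr(net_b)
  obs <- .hub_from_adjacency(.adj_from_repr(ra)) -
    .hub_from_adjacency(.adj_from_repr(rb))
  null <- .with_seed(seed, {
    sa <- as.integer(nswap_factor * nrow(ra$edges))
    sb <- as.integer(nswap_factor * nrow(rb$edges))
    t(vapply(seq_len(n_perm), function(k) {
      ea <- .rewire_edges_cpp(ra$edges, sa, 100L * sa)
      eb <- .rewire_edges_cpp(rb$edges, sb, 100L * sb)
      .hub_from_adjacency(.adj_from_repr(list(edges = ea, weights = ra$weights, n = ra$n))) -
        .hub_from_adjacency(.adj_from_repr(list(edges = eb, weights = rb$weights, n = rb$n)))
    }, numeric(length(nodes))))
  })
  p <- vapply(seq_along(nodes), function(j) {
    (sum(abs(null[, j]) >= abs(obs[j])) + 1) / (n_perm + 1)
  }, numeric(1))
  structure(list(table = data.frame(node = nodes, observed = unname(obs),
                                    p = p),
                 null = null, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result>", x$n_perm, "rewired draws\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-node Pearson correlation between hub scores and behaviour
#'
#' Correlates each region's per-animal hub score (typically from the final
#' time bin's individual networks) with per-animal late extinction-learning
#' performance, pooled across groups.
#'
#' @param hub_table data.frame (animal_id, node, hub_score), one row per
#'   animal x node.
#' @param behavior data.frame with animal_id and percent_correct for the
#'   behaviour block of interest (one row per animal).
#' @return data.frame (node, r, p, n) of class `behavior_correlation`.
#' @export
behavior_hub_correlation <- function(hub_table, behavior) {
  stopifnot(all(c("animal_id", "node", "hub_score") %in% names(hub_table)),
            all(c("animal_id", "percent_correct") %in% names(behavior)))
  if (anyDuplicated(behavior$animal_id))
    stop("behavior must have one row per animal")
  common <- intersect(unique(hub_table$animal_id), behavior$animal_id)
  if (length(common) < 3) stop("need >= 3 matched animals")
  beh <- stats::setNames(behavior$percent_correct, behavior$animal_id)[common]
  if (stats::sd(beh) == 0) stop("zero-variance behaviour vector")
  out <- do.call(rbind, lapply(split(hub_table, hub_table$node), function(d) {
    h <- stats::setNames(d$hub_score, d$animal_id)[common]
    if (stats::sd(h) == 0)
      return(data.frame(node = d$node[1], r = NA_real_, p = NA_real_,
                        n = length(common)))
    ct <- stats::cor.test(h, beh, method = "pearson")
    data.frame(node = d$node[1], r = unname(ct$estimate), p = ct$p.value,
               n = length(common))
  }))
  rownames(out) <- NULL
  class(out) <- c("behavior_correlation", "data.frame")
  out
}
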