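#' Spearman correlation matrix for one time bin
#'
#' Computes Spearman's rho between the BOLD signals of all region pairs within
#' one time bin, with two-sided p-values and Bonferroni adjustment over the
#' m = C(n_regions, 2) unordered pairs. Ties are handled by midranks; p-values
#' use the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` by default,
#' with the exact permutation distribution available for small bins.
#'
#' @param ts A [roi_timeseries()].
#' @param bin_index Which bin to correlate (1-based).
#' @param p_method "t" (default) or "exact" (delegates to [stats::cor.test()],
#'   only sensible for < 10 samples).
#' @return A list of class `correlation_matrix` with `rho`, `p_raw`, `p_adj`
#'   (all symmetric, unit/NA diagonal), `m`, `n_samples`, `animal_id`,
#'   `group`, `bin`.
#' @export
build_spearman_matrix <- function(ts, bin_index, p_method = c("t", "exact")) {
  stopifnot(inherits(ts, "roi_timeseries"))
  p_method <- match.arg(p_method)
  nb <- length(ts$bin_edges) - 1L
  if (bin_index < 1 || bin_index > nb) stop("bin_index out of range")
  idx <- (ts$bin_edges[bin_index] + 1L):ts$bin_edges[bin_index + 1L]
  x <- ts$samples[, idx, drop = FALSE]
  n <- ncol(x)
  if (n < 3) stop("need at least 3 samples per bin")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s) in bin ", bin_index, ": ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  nr <- nrow(x)
  m <- nr * (nr - 1L) / 2L

  rho <- stats::cor(t(x), method = "spearman")
  if (p_method == "t") {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p_raw <- 2 * stats::pt(-abs(tt), df = n - 2)
    p_raw[abs(rho) >= 1] <- 0
  } else {
    p_raw <- matrix(NA_real_, nr, nr, dimnames = dimnames(rho))
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        p <- suppressWarnings(
          stats::cor.test(x[i, ], x[j, ], method = "spearman")$p.value)
        p_raw[i, j] <- p_raw[j, i] <- p
      }
    }
  }
  diag(p_raw) <- NA_real_
  p_adj <- pmin(m * p_raw, 1)  # pmin keeps the matrix argument's attributes
  structure(list(rho = rho, p_raw = p_raw, p_adj = p_adj, m = m,
                 n_samples = n, animal_id = ts$animal_id,
                 group = ts$group, bin = bin_index),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>", nrow(x$rho), "regions, bin", x$bin,
      "- animal", x$animal_id, "(", x$group, "),", x$n_samples,
      "samples, Bonferroni family m =", x$m, "\n")
  invisible(x)
}

# igraph with all nodes, provenance graph attributes; internal constructor.
.functional_network <- function(edges, nodes, provenance = "network") {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges$from, nodes),
                                    match(edges$to, nodes)))
    igraph::E(g)$weight <- edges$weight
  } else {
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  }
  igraph::graph_attr(g, "provenance") <- provenance
  g
}

#' Threshold a correlation matrix into a functional network
#'
#' Retains the edge (i, j) iff the Bonferroni-adjusted two-sided p-value is
#' below `alpha` and rho is positive; the retained rho becomes the edge
#' weight. All regions stay as nodes, so isolated nodes are possible.
#'
#' @param cm A [build_spearman_matrix()] result.
#' @param alpha Significance level on the adjusted p-value (default 0.001).
#' @return An igraph graph (weighted, undirected, named nodes) with a
#'   `provenance` graph attribute.
#' @export
threshold_to_network <- function(cm, alpha = 0.001) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  nodes <- rownames(cm$rho)
  ut <- upper.tri(cm$rho)
  keep <- which(ut & cm$p_adj < alpha & cm$rho > 0, arr.ind = TRUE)
  edges <- data.frame(from = nodes[keep[, 1]], to = nodes[keep[, 2]],
                      weight = cm$rho[keep])
  .functional_network(edges, nodes,
                      provenance = sprintf("animal=%s bin=%d alpha=%g",
                                           cm$animal_id, cm$bin, alpha))
}

#' Group consensus network
#'
#' Retains an edge iff it is present (significant and positive) in at least
#' `min_fraction` of the individual networks; its weight is the mean rho over
#' the individual networks in which it was significant. The per-edge share of
#' networks containing it is stored as edge attribute `retention_fraction`.
#'
#' @param networks List of thresholded individual networks over an identical
#'   node set.
#' @param min_fraction Minimum retention fraction (default 0.75).
#' @param average_over "significant" (default: mean over the networks where
#'   the edge passed threshold, the literal consensus rule) or "all" (mean
#'   over every network's rho, significant or not, for sensitivity analysis;
#'   requires `cms`).
#' @param cms Optional list of matching [build_spearman_matrix()] results
#'   (needed for `average_over = "all"`).
#' @return An igraph graph with edge attributes `weight` and
#'   `retention_fraction` and graph attribute `min_fraction`.
#' @export
build_consensus_network <- function(networks, min_fraction = 0.75,
                                    average_over = c("significant", "all"),
                                    cms = NULL) {
  average_over <- match.arg(average_over)
  if (length(networks) < 2) stop("need at least 2 networks")
  nodes <- igraph::V(networks[[1]])$name
  for (g in networks)
    if (!identical(igraph::V(g)$name, nodes))
      stop("mismatched node sets across networks")
  if (average_over == "all" && is.null(cms))
    stop("average_over = 'all' requires cms")

  n <- length(nodes)
  k <- length(networks)
  count <- matrix(0, n, n)
  wsum <- matrix(0, n, n)
  for (g in networks) {
    a <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    count <- count + (a > 0)
    wsum <- wsum + a
  }
  frac <- count / k
  keep <- which(upper.tri(frac) & frac >= min_fraction, arr.ind = TRUE)
  if (average_over == "significant") {
    w <- wsum[keep] / count[keep]
  } else {
    rsum <- Reduce(`+`, lapply(cms, function(cm) cm$rho))
    w <- rsum[keep] / k
  }
  edges <- data.frame(from = nodes[keep[, 1]], to = nodes[keep[, 2]],
                      weight = w)
  g <- .functional_network(edges, nodes,
                           provenance = sprintf("consensus k=%d min_fraction=%g",
                                                k, min_fraction))
  if (igraph::ecount(g) > 0) igraph::E(g)$retention_fraction <- frac[keep]
  igraph::graph_attr(g, "min_fraction") <- min_fraction
  g
}

#' Write a network as GraphML and as an edge-list CSV
#'
#' @param net igraph network.
#' @param graphml_path,edgelist_path Output paths (either may be NULL to
#'   skip).
#' @return Invisibly, the edge-list data.frame.
#' @export
write_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("source", "target")
  if (!is.null(edgelist_path))
    utils::write.csv(el, edgelist_path, row.names = FALSE)
  invisible(el)
}

#' Correlation matrix in long format
#'
#' @param cm A [build_spearman_matrix()] result.
#' @param path Optional CSV output path.
#' @return data.frame (region_i, region_j, rho, p_raw, p_adj), upper
#'   triangle only.
#' @export
correlation_long <- function(cm, path = NULL) {
  nodes <- rownames(cm$rho)
  ut <- which(upper.tri(cm$rho), arr.ind = TRUE)
  df <- data.frame(region_i = nodes[ut[, 1]], region_j = nodes[ut[, 2]],
                   rho = cm$rho[ut], p_raw = cm$p_raw[ut],
                   p_adj = cm$p_adj[ut])
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Write a cohort to per-animal CSV files plus manifest and behaviour tables
#'
#' One delimited file per animal (rows = regions, columns = samples, first
#' column the region name), a manifest (animal_id, group, file, bin edges)
#' and the behaviour table, all plain CSV.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(cohort$timeseries, function(ts) {
    file <- file.path(dir, paste0(ts$animal_id, ".csv"))
    df <- data.frame(region = ts$region_names, ts$samples,
                     check.names = FALSE)
    utils::write.csv(df, file, row.names = FALSE)
    data.frame(animal_id = ts$animal_id, group = ts$group,
               file = basename(file),
               bin_edges = paste(ts$bin_edges, collapse = ";"))
  }))
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing manifest.csv, behavior.csv and per-animal
#'   files.
#' @return A list with `timeseries` and `behavior` (no `truth`: planted
#'   ground truth is not part of the on-disk interchange format).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv found in ", dir)
  manifest <- utils::read.csv(mpath)
  ts_list <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- utils::read.csv(file.path(dir, manifest$file[i]), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(df[[1]], NULL)
    roi_timeseries(manifest$animal_id[i], manifest$group[i], m,
                   as.integer(strsplit(manifest$bin_edges[i], ";")[[1]]))
  })
  names(ts_list) <- manifest$animal_id
  behavior_path <- file.path(dir, "behavior.csv")
  behavior <- if (file.exists(behavior_path))
    utils::read.csv(behavior_path) else NULL
  list(timeseries = ts_list, behavior = behavior)
}
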