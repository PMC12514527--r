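#' Pipeline configuration
#'
#' Collects every stage parameter of the full analysis. Input is either a
#' directory previously written by [write_cohort()] (`input_dir`) or a
#' synthetic [cohort_config()] (`cohort`); exactly one must be given.
#'
#' @param cohort Optional [cohort_config()] for synthetic input.
#' @param input_dir Optional directory with manifest.csv / per-animal CSVs /
#'   behavior.csv.
#' @param alpha Edge-significance level on Bonferroni-adjusted p-values
#'   (default 0.001).
#' @param min_fraction Consensus retention fraction (default 0.75).
#' @param role_quantile Upper-quantile cut for hub/connector flags
#'   (default 0.20).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param n_perm Rewiring permutation draws (default 1000).
#' @param theta,max_iterations Disruption-propagation parameters.
#' @param baseline_bin Baseline bin for normalisation (default 1).
#' @param behavior_session,behavior_block Behaviour block used for the
#'   hub-behaviour correlation (default session "EL2", block 2: the late
#'   extinction block).
#' @param seed Master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL,
                            alpha = 0.001, min_fraction = 0.75,
                            role_quantile = 0.20, n_boot = 1000L,
                            n_perm = 1000L, theta = 0.5,
                            max_iterations = NULL, baseline_bin = 1L,
                            behavior_session = "EL2", behavior_block = 2L,
                            seed = 1L) {
  if (is.null(cohort) == is.null(input_dir))
    stop("give exactly one of cohort or input_dir")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  if (role_quantile <= 0 || role_quantile >= 1)
    stop("role_quantile must be in (0, 1)")
  structure(list(cohort = cohort, input_dir = input_dir, alpha = alpha,
                 min_fraction = min_fraction, role_quantile = role_quantile,
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 theta = theta, max_iterations = max_iterations,
                 baseline_bin = as.integer(baseline_bin),
                 behavior_session = behavior_session,
                 behavior_block = as.integer(behavior_block),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments; an optional `cohort`
#' mapping holds [cohort_config()] arguments for synthetic input.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_config, y$cohort)
  do.call(pipeline_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: generate/load the cohort; per-animal, per-bin Spearman
#' correlation matrices; thresholding into individual networks; per-network
#' global metrics and mean hub score; baseline normalisation; final-bin group
#' consensus networks; Louvain communities, diversity scores and node roles;
#' BCa bootstrap group contrasts on the normalised metrics; rewiring
#' permutation test on consensus hub scores; disruption-propagation lesion
#' profiles; hub-behaviour correlation; and the behaviour-seeded minimal
#' network. All tables, networks (GraphML + edge lists) and a JSON summary
#' (with every effective parameter and the seed) are written to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- .stage("input", {
    if (!is.null(config$cohort)) {
      co <- generate_cohort(config$cohort)
      write_cohort(co, file.path(out_dir, "cohort"))
      co
    } else read_cohort(config$input_dir)
  })
  ts_list <- cohort$timeseries
  n_bins <- length(ts_list[[1]]$bin_edges) - 1L
  groups <- unique(vapply(ts_list, `[[`, character(1), "group"))

  nets <- .stage("correlate/threshold", {
    lapply(ts_list, function(ts) lapply(seq_len(n_bins), function(b) {
      cm <- build_spearman_matrix(ts, b)
      list(cm = cm, net = threshold_to_network(cm, alpha = config$alpha))
    }))
  })

  metrics <- .stage("metrics", {
    do.call(rbind, lapply(names(nets), function(id) {
      do.call(rbind, lapply(seq_len(n_bins), function(b) {
        g <- nets[[id]][[b]]$net
        gm <- network_metrics(g)
        hs <- suppressWarnings(hub_scores(g))
        data.frame(animal_id = id, group = ts_list[[id]]$group, bin = b,
                   metric = c(names(gm), "mean_hub_score"),
                   value = c(as.numeric(gm[1, ]), mean(hs)))
      }))
    }))
  })
  utils::write.csv(metrics, file.path(out_dir, "metrics_raw.csv"),
                   row.names = FALSE)

  normalized <- .stage("normalize", {
    do.call(rbind, lapply(split(metrics, metrics$metric), function(d) {
      base_ok <- all(tapply(d$value[d$bin == config$baseline_bin],
                            d$group[d$bin == config$baseline_bin], mean) != 0)
      if (!base_ok) return(NULL)
      normalize_to_baseline(d, baseline_bin = config$baseline_bin)
    }))
  })
  utils::write.csv(normalized, file.path(out_dir, "metrics_normalized.csv"),
                   row.names = FALSE)

  consensus <- .stage("consensus", {
    out <- lapply(groups, function(grp) {
      ids <- names(ts_list)[vapply(ts_list, `[[`, character(1), "group") == grp]
      build_consensus_network(lapply(ids, function(id) nets[[id]][[n_bins]]$net),
                              min_fraction = config$min_fraction)
    })
    names(out) <- groups
    for (grp in groups)
      write_network(out[[grp]],
                    file.path(out_dir, paste0("consensus_", grp, ".graphml")),
                    file.path(out_dir, paste0("consensus_", grp, "_edges.csv")))
    out
  })

  roles <- .stage("communities/roles", {
    out <- lapply(groups, function(grp) {
      g <- consensus[[grp]]
      part <- detect_communities(g, seed = config$seed)
      hs <- suppressWarnings(hub_scores(g))
      div <- diversity_scores(g, part)
      tab <- classify_node_roles(hs, div, quantile = config$role_quantile)
      tab$community <- unname(part$membership[tab$node])
      list(partition = part, table = tab)
    })
    names(out) <- groups
    for (grp in groups)
      utils::write.csv(out[[grp]]$table,
                       file.path(out_dir, paste0("node_roles_", grp, ".csv")),
                       row.names = FALSE)
    out
  })

  boots <- .stage("bootstrap", {
    if (length(groups) != 2 || is.null(normalized)) NULL else {
      .with_seed(config$seed, {
        do.call(rbind, lapply(split(normalized, normalized$metric), function(d) {
          do.call(rbind, lapply(setdiff(sort(unique(d$bin)), config$baseline_bin),
                                function(b) {
            a <- d$normalized[d$bin == b & d$group == groups[2]]
            bb <- d$normalized[d$bin == b & d$group == groups[1]]
            br <- bootstrap_group_difference(a, bb, n_boot = config$n_boot,
                                            metric = d$metric[1])
            data.frame(metric = d$metric[1], bin = b, observed = br$observed,
                       stars = br$stars,
                       ci95_lower = br$ci$lower[1], ci95_upper = br$ci$upper[1],
                       ci99_lower = br$ci$lower[2], ci99_upper = br$ci$upper[2],
                       ci999_lower = br$ci$lower[3], ci999_upper = br$ci$upper[3])
          }))
        }))
      })
    }
  })
  if (!is.null(boots))
    utils::write.csv(boots, file.path(out_dir, "bootstrap_contrasts.csv"),
                     row.names = FALSE)

  perm <- .stage("permutation", {
    if (length(groups) != 2) NULL else
      rewire_permutation_test(consensus[[groups[2]]], consensus[[groups[1]]],
                              n_perm = config$n_perm, seed = config$seed)
  })
  if (!is.null(perm))
    utils::write.csv(perm$table, file.path(out_dir, "hub_permutation.csv"),
                     row.names = FALSE)

  disruption <- .stage("disruption", {
    pars <- disruption_params(config$theta, config$max_iterations)
    out <- lapply(groups, function(grp) disruption_profile(consensus[[grp]], pars))
    names(out) <- groups
    for (grp in groups)
      utils::write.csv(out[[grp]]$table,
                       file.path(out_dir, paste0("disruption_", grp, ".csv")),
                       row.names = FALSE)
    out
  })

  behavior_cor <- .stage("behavior", {
    beh <- cohort$behavior
    if (is.null(beh)) {
      message("behavior table absent: skipping hub-behaviour correlation ",
              "and minimal network")
      NULL
    } else {
      late <- beh[beh$session == config$behavior_session &
                  beh$block_index == config$behavior_block, ]
      hub_table <- do.call(rbind, lapply(names(nets), function(id) {
        hs <- suppressWarnings(hub_scores(nets[[id]][[n_bins]]$net))
        data.frame(animal_id = id, node = names(hs), hub_score = unname(hs))
      }))
      bc <- behavior_hub_correlation(hub_table, late)
      utils::write.csv(bc, file.path(out_dir, "behavior_hub_correlation.csv"),
                       row.names = FALSE)
      bc
    }
  })

  minimal <- .stage("minimal", {
    if (is.null(behavior_cor) || length(groups) != 2) NULL else {
      seeds <- suppressWarnings(select_behavior_hubs(behavior_cor, alpha = 0.05))
      if (length(seeds) == 0) {
        message("no behaviour-correlated seed regions; minimal network skipped")
        NULL
      } else {
        mn <- extract_minimal_network(consensus[[groups[2]]], seeds,
                                      seed = config$seed)
        write_network(mn$graph,
                      file.path(out_dir, "minimal_network.graphml"),
                      file.path(out_dir, "minimal_network_edges.csv"))
        utils::write.csv(rank_minimal_centralities(mn),
                         file.path(out_dir, "minimal_rankings.csv"),
                         row.names = FALSE)
        mn
      }
    }
  })

  summary <- list(
    parameters = config[setdiff(names(config), c("cohort", "input_dir"))],
    synthetic = !is.null(config$cohort),
    n_animals = length(ts_list), n_bins = n_bins, groups = as.list(groups),
    consensus_modularity = lapply(roles, function(x) x$partition$modularity),
    n_significant_hub_nodes = if (is.null(perm)) NULL else
      sum(perm$table$p < 0.05),
    significant_hub_nodes = if (is.null(perm)) NULL else
      as.list(perm$table$node[perm$table$p < 0.05]),
    disruption_hub_correlation = lapply(disruption, function(d) d$correlation$r),
    behavior_seed_regions = if (is.null(minimal)) NULL else
      as.list(minimal$seeds),
    minimal_network_size = if (is.null(minimal)) NULL else
      length(minimal$members))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(cohort = cohort, networks = nets, metrics = metrics,
                 normalized = normalized, consensus = consensus,
                 roles = roles, bootstrap = boots, permutation = perm,
                 disruption = disruption, behavior_correlation = behavior_cor,
                 minimal = minimal, summary = summary))
}
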