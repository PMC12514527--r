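#' Default brain region labels
#'
#' The 21 bilateral regions of interest from which BOLD time series are
#' extracted: hippocampal subfields (dorsal and ventral DG/CA3/CA1), dorsal
#' subiculum and postsubiculum, thalamic nuclei (RE, LDT, PVT), nucleus
#' accumbens, prefrontal areas (ORB, IL, PrL), retrosplenial segments
#' (a/i/pRSP), cingulate segments (a/pACC) and posterior parietal cortex.
#'
#' @return Character vector of 21 region labels.
#' @export
default_region_names <- function() {
  c("dDG", "dCA3", "dCA1", "vDG", "vCA3", "vCA1", "SUBd", "PoS",
    "RE", "LDT", "PVT", "NAc", "ORB", "IL", "PrL",
    "aRSP", "iRSP", "pRSP", "aACC", "pACC", "PPC")
}

#' Default latent community assignment
#'
#' Three latent communities mirroring the resting-state organisation seen in
#' control animals: a dorsal-hippocampal community (with RE, PPC and aRSP), a
#' ventral-hippocampal community (with subiculum and i/pRSP) and a prefrontal
#' community (with cingulate, accumbens and the LDT/PVT thalamic relays).
#'
#' @return Named character vector mapping each region to a community label.
#' @export
default_community_assignment <- function() {
  c(dDG = "dorsal", dCA3 = "dorsal", dCA1 = "dorsal",
    RE = "dorsal", PPC = "dorsal", aRSP = "dorsal",
    vDG = "ventral", vCA3 = "ventral", vCA1 = "ventral",
    SUBd = "ventral", PoS = "ventral", iRSP = "ventral", pRSP = "ventral",
    ORB = "prefrontal", IL = "prefrontal", PrL = "prefrontal",
    aACC = "prefrontal", pACC = "prefrontal", NAc = "prefrontal",
    LDT = "prefrontal", PVT = "prefrontal")
}

#' Synthetic cohort configuration
#'
#' Parameters of the latent-factor generator that emulates a two-group
#' chemogenetic-reactivation fMRI cohort: each region's BOLD-like signal is a
#' loading on its community's latent factor plus (for hub regions)
#' cross-community loadings, plus white Gaussian noise. In the reactivation
#' group, hub-region coupling is boosted from the second time bin onwards
#' (the bins after agonist injection).
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_per_group Animals per group (default 8).
#' @param region_names Character vector of region labels (default the 21
#'   regions of [default_region_names()]).
#' @param samples_per_bin Samples per time bin (default 900: 15 min at
#'   TR = 1 s).
#' @param n_bins Number of time bins (default 4; bin 1 is baseline, the
#'   coupling boost applies to bins >= 2).
#' @param community_assignment Named vector region -> latent community.
#' @param community_coupling Named vector of per-community loading strengths
#'   (default: ventral strongest at 1.3, dorsal 1.0, prefrontal 0.85;
#'   communities not listed default to 1). Grading the couplings makes the
#'   baseline network's eigenvector centrality concentrate stably on one
#'   community — the way anaesthetised baseline recordings are dominated by
#'   one strongly coherent cluster — so the post-injection rise of the hub
#'   regions is a well-defined planted contrast.
#' @param hub_regions Regions receiving cross-community loadings and the
#'   reactivation-group coupling boost.
#' @param hub_gain Dimensionless coupling boost for hub regions in the
#'   reactivation group, bins >= 2 (default 1.5; 0 disables the planted
#'   effect).
#' @param noise_sd Standard deviation of the additive white noise (default 1).
#' @param behavior_coupling Slope (percentage points per unit of planted hub
#'   strength) linking an animal's realised hub gain to its late
#'   extinction-learning performance (default 15).
#' @param global_loading Mean loading of regions on a shared global
#'   fluctuation (default 0.5), emulating the widespread positive BOLD
#'   correlations of real recordings.
#' @param global_loading_spread Range of the region-graded global loadings
#'   (default 0.2): region r receives a fixed loading
#'   `global_loading + global_loading_spread * (rank(r)/(n-1) - 0.5)`, so
#'   cross-community correlations straddle the significance boundary the way
#'   heterogeneous real data do (some pairs stably connected, some stably
#'   not, some borderline).
#' @param hub_base_cross Baseline cross-community loading of hub regions
#'   (default 0: hubs are unremarkable before the injection; the planted
#'   hub contrast exists only in the boosted bins).
#' @param hub_own_frac,hub_cross_frac Fractions of the realised hub gain added
#'   to the own-community and cross-community loadings respectively
#'   (defaults 0.4 and 0.3).
#' @param hub_gain_cv Lognormal coefficient of variation of the per-animal
#'   realised hub gain (default 0.1), the inter-animal variability that the
#'   behaviour coupling acts on.
#' @param behavior_noise_sd Noise (percentage points) on behaviour scores
#'   (default 5).
#' @param ar_coef AR(1) coefficient for temporal autocorrelation of factors
#'   and noise (default 0: white).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_per_group = 8L,
                          region_names = default_region_names(),
                          samples_per_bin = 900L,
                          n_bins = 4L,
                          community_assignment = default_community_assignment(),
                          community_coupling = c(dorsal = 1, ventral = 1.3,
                                                 prefrontal = 0.85),
                          hub_regions = c("dDG", "dCA3", "dCA1", "RE", "PVT"),
                          hub_gain = 1.5,
                          noise_sd = 1,
                          behavior_coupling = 15,
                          global_loading = 0.5,
                          global_loading_spread = 0.2,
                          hub_base_cross = 0,
                          hub_own_frac = 0.4,
                          hub_cross_frac = 0.3,
                          hub_gain_cv = 0.1,
                          behavior_noise_sd = 5,
                          ar_coef = 0) {
  if (samples_per_bin <= 0) stop("samples_per_bin must be positive")
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (hub_gain < 0) stop("hub_gain must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (anyDuplicated(region_names)) stop("region_names must be unique")
  missing_comm <- setdiff(region_names, names(community_assignment))
  if (length(missing_comm) > 0)
    stop("regions without a community assignment: ",
         paste(missing_comm, collapse = ", "))
  bad_hub <- setdiff(hub_regions, region_names)
  if (length(bad_hub) > 0)
    stop("unknown region in hub_regions: ", paste(bad_hub, collapse = ", "))
  if (abs(ar_coef) >= 1) stop("ar_coef must be in (-1, 1)")
  structure(list(seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group),
                 region_names = region_names,
                 samples_per_bin = as.integer(samples_per_bin),
                 n_bins = as.integer(n_bins),
                 community_assignment = community_assignment[region_names],
                 community_coupling = community_coupling,
                 hub_regions = hub_regions,
                 hub_gain = hub_gain,
                 noise_sd = noise_sd,
                 behavior_coupling = behavior_coupling,
                 global_loading = global_loading,
                 global_loading_spread = global_loading_spread,
                 hub_base_cross = hub_base_cross,
                 hub_own_frac = hub_own_frac,
                 hub_cross_frac = hub_cross_frac,
                 hub_gain_cv = hub_gain_cv,
                 behavior_noise_sd = behavior_noise_sd,
                 ar_coef = ar_coef),
            class = "cohort_config")
}

# AR(1)-filter the rows of a white-noise matrix; ar = 0 is a no-op.
.ar1_rows <- function(m, ar) {
  if (ar == 0) return(m)
  t(apply(m, 1, function(x) as.numeric(stats::filter(x, ar, "recursive")))) *
    sqrt(1 - ar^2)
}

#' One animal's regional time-series container
#'
#' @param animal_id Animal label.
#' @param group Group label (e.g. "control" or "reactivation").
#' @param samples Numeric matrix, regions x time, with region rownames.
#' @param bin_edges Integer vector of length n_bins + 1; bin b covers samples
#'   `(bin_edges[b] + 1):bin_edges[b + 1]`.
#' @return A list of class `roi_timeseries`.
#' @export
roi_timeseries <- function(animal_id, group, samples, bin_edges) {
  if (is.null(rownames(samples))) stop("samples must have region rownames")
  if (anyDuplicated(rownames(samples))) stop("region names must be unique")
  bin_edges <- as.integer(bin_edges)
  if (bin_edges[1] != 0L || bin_edges[length(bin_edges)] != ncol(samples) ||
      any(diff(bin_edges) < 3L))
    stop("bin_edges must start at 0, end at ncol(samples), and give >= 3 samples per bin")
  structure(list(animal_id = animal_id, group = group,
                 region_names = rownames(samples),
                 samples = samples, bin_edges = bin_edges),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> animal", x$animal_id, "group", x$group, "-",
      nrow(x$samples), "regions x", ncol(x$samples), "samples,",
      length(x$bin_edges) - 1L, "bins\n")
  invisible(x)
}

#' Generate a synthetic two-group cohort
#'
#' Draws BOLD-like regional time series and extinction-learning behaviour for
#' a control and a reactivation group under the latent-factor model described
#' in [cohort_config()]. Each animal in the reactivation group receives a
#' realised hub gain (lognormal around `hub_gain`); that planted per-animal
#' hub strength also drives its late extinction-learning performance through
#' `behavior_coupling`, while control behaviour decays towards the 50 %
#' chance level across extinction blocks.
#'
#' @param config A [cohort_config()].
#' @return A list with `timeseries` (list of [roi_timeseries()]),
#'   `behavior` (data.frame: animal_id, group, session, block_index,
#'   percent_correct), and `truth` (data.frame of planted per-animal hub
#'   strengths).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  regions <- config$region_names
  nr <- length(regions)
  comms <- config$community_assignment
  comm_levels <- unique(comms)
  nc <- length(comm_levels)
  spb <- config$samples_per_bin
  is_hub <- regions %in% config$hub_regions
  groups <- c("control", "reactivation")

  # fixed per-region global loadings (anatomy-like: constant across animals)
  gl <- config$global_loading +
    config$global_loading_spread * (seq_len(nr) - 1) / max(nr - 1, 1) -
    config$global_loading_spread / 2

  ts_list <- list()
  truth <- data.frame(animal_id = character(0), group = character(0),
                      hub_strength = numeric(0))
  for (grp in groups) {
    for (i in seq_len(config$n_per_group)) {
      id <- sprintf("%s_%02d", ifelse(grp == "control", "ctl", "rea"), i)
      g_a <- if (grp == "reactivation" && config$hub_gain > 0)
        config$hub_gain * exp(stats::rnorm(1, 0, config$hub_gain_cv)) else 0
      bins <- vector("list", config$n_bins)
      for (b in seq_len(config$n_bins)) {
        boosted <- grp == "reactivation" && b >= 2L
        g_eff <- if (boosted) g_a else 0
        # loading matrix: regions x communities
        cpl <- vapply(comm_levels, function(cm) {
          v <- config$community_coupling[cm]
          if (is.na(v)) 1 else unname(v)
        }, numeric(1))
        L <- matrix(0, nr, nc, dimnames = list(regions, comm_levels))
        own_idx <- match(comms, comm_levels)
        L[cbind(seq_len(nr), own_idx)] <- cpl[own_idx]
        if (any(is_hub)) {
          for (r in which(is_hub)) {
            own <- own_idx[r]
            L[r, own] <- cpl[own] * (1 + config$hub_own_frac * g_eff)
            L[r, -own] <- config$hub_base_cross + config$hub_cross_frac * g_eff
          }
        }
        f <- .ar1_rows(matrix(stats::rnorm(nc * spb), nc, spb), config$ar_coef)
        glob <- .ar1_rows(matrix(stats::rnorm(spb), 1, spb), config$ar_coef)
        eps <- .ar1_rows(matrix(stats::rnorm(nr * spb), nr, spb), config$ar_coef)
        bins[[b]] <- L %*% f + gl %o% as.numeric(glob) +
          config$noise_sd * eps
      }
      samples <- do.call(cbind, bins)
      rownames(samples) <- regions
      ts_list[[id]] <- roi_timeseries(id, grp, samples,
                                      bin_edges = spb * (0:config$n_bins))
      truth <- rbind(truth, data.frame(animal_id = id, group = grp,
                                       hub_strength = g_a))
    }
  }

  behavior <- .generate_behavior(truth, config)
  list(timeseries = ts_list, behavior = behavior, truth = truth)
}

# Extinction-learning behaviour: 2 sessions x 2 blocks of 10 trials.
# Controls extinguish (decay towards 50 % chance); reactivation animals
# sustain performance in proportion to their planted hub strength.
.generate_behavior <- function(truth, config) {
  sessions <- c("EL1", "EL2")
  blocks <- 1:2
  out <- do.call(rbind, lapply(seq_len(nrow(truth)), function(k) {
    row <- truth[k, ]
    df <- expand.grid(session = sessions, block_index = blocks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df <- df[order(df$session, df$block_index), ]
    overall_block <- seq_len(nrow(df))
    base <- if (row$group == "control") {
      50 + 30 * exp(-0.9 * (overall_block - 1))
    } else {
      pmax(50 + config$behavior_coupling * row$hub_strength, 50)
    }
    pc <- pmin(100, pmax(0, base + stats::rnorm(nrow(df), 0, config$behavior_noise_sd)))
    data.frame(animal_id = row$animal_id, group = row$group,
               session = df$session, block_index = df$block_index,
               percent_correct = pc)
  }))
  rownames(out) <- NULL
  out
}

#' Deterministic toy graphs for oracle tests
#'
#' @param kind One of "complete", "star", "path", "ring",
#'   "planted_partition".
#' @param n Number of nodes (>= 2).
#' @param weight Uniform edge weight (default 1).
#' @param p_in,p_out Within/between-block edge probabilities
#'   (planted_partition only).
#' @param communities Named or plain vector of block labels, length n
#'   (planted_partition only; default 3 equal blocks).
#' @param seed Seed for the planted-partition draw.
#' @return An igraph graph with a `weight` edge attribute and node names
#'   `v1..vn` (star graphs have the center first).
#' @export
generate_toy_graph <- function(kind, n, weight = 1,
                               p_in = 0.9, p_out = 0.05,
                               communities = NULL, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  if (weight <= 0) stop("weight must be positive")
  g <- switch(kind,
    complete = igraph::make_full_graph(n),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    path = igraph::make_ring(n, circular = FALSE),
    ring = igraph::make_ring(n, circular = TRUE),
    planted_partition = {
      if (is.null(communities))
        communities <- sort(rep(seq_len(3), length.out = n))
      if (length(communities) != n) stop("communities must have length n")
      sizes <- as.vector(table(factor(communities, levels = unique(communities))))
      pm <- matrix(p_out, length(sizes), length(sizes))
      diag(pm) <- p_in
      set.seed(seed)
      gg <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
      igraph::V(gg)$block <- rep(unique(communities), sizes)
      gg
    },
    stop("unknown toy graph kind: ", kind)
  )
  igraph::V(g)$name <- paste0("v", seq_len(n))
  igraph::E(g)$weight <- weight
  g
}
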