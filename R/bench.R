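#' Select stratified seed nodes across the expected-force range
#'
#' Implements the binned seed-selection protocol: hubs are removed, the
#' observed ExF range of the remaining nodes is split into `n_bins`
#' equal-width bins (last bin right-closed), and `seeds_per_bin` nodes are
#' drawn uniformly without replacement from each bin; bins with fewer members
#' contribute all of them. With 15 bins and 5 seeds per bin this yields about
#' 75 seeds on a typical 1,000-node scale-free network.
#'
#' @param scores a node score table (e.g. from [expected_force_all()] or
#'   [node_score_table()]) with columns `node`, `exf` and `excluded_as_hub`.
#' @param n_bins number of equal-width bins.
#' @param seeds_per_bin seeds drawn per occupied bin.
#' @return character vector of selected node identifiers.
#' @export
select_seeds <- function(scores, n_bins = 15, seeds_per_bin = 5) {
  stopifnot(n_bins >= 1, seeds_per_bin >= 1)
  if (!all(c("node", "exf") %in% names(scores)))
    stop("scores must have columns 'node' and 'exf'")
  if ("excluded_as_hub" %in% names(scores))
    scores <- scores[!scores$excluded_as_hub, , drop = FALSE]
  scores <- scores[!is.na(scores$exf), , drop = FALSE]
  if (nrow(scores) == 0) stop("no scored non-hub nodes to select from")
  e <- scores$exf
  rng <- range(e)
  bin <- if (rng[1] == rng[2]) rep(1L, length(e)) else
    pmin(n_bins, 1L + as.integer(floor((e - rng[1]) / diff(rng) * n_bins)))
  unlist(lapply(split(as.character(scores$node), bin), function(members) {
    if (length(members) <= seeds_per_bin) members
    else sample(members, seeds_per_bin)
  }), use.names = FALSE)
}

#' Correlate a node metric with an epidemic outcome
#'
#' Pearson (default) correlation over seeds. For time-to-half-coverage
#' outcomes the absolute value is reported, since spreading power shortens
#' the time to half coverage. Returns `NA` (with a warning) when either
#' column is constant.
#'
#' @param metric numeric vector of node metric values.
#' @param outcome numeric vector of per-seed outcomes (same length).
#' @param outcome_kind `"epo"` or `"tthc"`.
#' @param method correlation estimator, `"pearson"` or `"spearman"`.
#' @return a correlation in `[-1, 1]`, or `NA`.
#' @export
correlate <- function(metric, outcome, outcome_kind = c("epo", "tthc"),
                      method = c("pearson", "spearman")) {
  outcome_kind <- match.arg(outcome_kind)
  method <- match.arg(method)
  ok <- stats::complete.cases(metric, outcome)
  if (sum(ok) < 3) stop("at least 3 seeds with both values are required")
  m <- metric[ok]; o <- outcome[ok]
  if (stats::var(m) == 0 || stats::var(o) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  r <- cor(m, o, method = method)
  if (outcome_kind == "tthc") abs(r) else r
}

#' First- and second-order degree decomposition of a node
#'
#' For each requested node returns its degree, the sum of the degrees of its
#' distance-1 neighbours, and the sum of the degrees of nodes at geodesic
#' distance 2 (each node counted once, at its geodesic distance). These are
#' the quantities whose correlation with ExF separates low- from
#' high-spreading-power nodes.
#'
#' @param net an igraph graph.
#' @param v node identifiers or indices; default all nodes.
#' @return a data frame with columns `node`, `degree`, `nbr_deg_1`,
#'   `nbr_deg_2`.
#' @export
degree_decomposition <- function(net, v = NULL) {
  idx <- resolve_nodes(net, v)
  deg <- igraph::degree(net)
  D <- igraph::distances(net, v = igraph::V(net)[idx])
  nbr1 <- apply(D, 1, function(d) sum(deg[d == 1]))
  nbr2 <- apply(D, 1, function(d) sum(deg[d == 2]))
  data.frame(node = node_ids(net)[idx], degree = as.integer(deg[idx]),
             nbr_deg_1 = as.numeric(nbr1), nbr_deg_2 = as.numeric(nbr2))
}

#' Agreement between two node metrics
#'
#' Top-k overlap (fraction of shared nodes among each metric's k top-ranked
#' nodes, ties broken by node identifier) and Spearman rank correlation over
#' all scored nodes.
#'
#' @param scores a node score table.
#' @param a,b column names of the two metrics.
#' @param k size of the top set.
#' @return a list with `top_k_overlap` and `rank_correlation`.
#' @export
metric_agreement <- function(scores, a, b, k = 10) {
  stopifnot(a %in% names(scores), b %in% names(scores))
  ok <- stats::complete.cases(scores[[a]], scores[[b]])
  s <- scores[ok, , drop = FALSE]
  if (k > nrow(s)) stop("k exceeds the number of scored nodes")
  top <- function(col) {
    ord <- order(-s[[col]], as.character(s$node))
    as.character(s$node)[ord[seq_len(k)]]
  }
  list(top_k_overlap = length(intersect(top(a), top(b))) / k,
       rank_correlation = cor(s[[a]], s[[b]], method = "spearman"))
}

#' Configure a family validation experiment
#'
#' Bundles every knob of the benchmarking protocol. Paper-scale defaults are
#' 100 networks, 5 seeds per bin (about 75 seeds) and 100 runs per seed;
#' desk-scale replications shrink `n_networks`, `seeds_per_bin` and
#' `runs_per_seed`.
#'
#' @param family `"pareto"` (Chung-Lu generator) or `"degseq"` (resampled
#'   degree sequence; supply `degree_seq`).
#' @param n_networks number of replicate networks.
#' @param n_nodes target giant-component size.
#' @param degree_seq empirical degree sequence for `family = "degseq"`.
#' @param weight_scheme edge-weight scheme (see [assign_weights()]).
#' @param model,time_mode spreading process and time discretization.
#' @param n_bins,seeds_per_bin,hub_fraction seed-selection protocol.
#' @param runs_per_seed outbreaks (or SI runs) per seed.
#' @param probe_runs outbreaks per seed per calibration probe.
#' @param x,alpha expected-force parameters.
#' @param master_seed RNG seed making the whole experiment reproducible.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(family = c("pareto", "degseq"),
                              n_networks = 100, n_nodes = 1000,
                              degree_seq = NULL,
                              weight_scheme = "unit",
                              model = c("SIS", "SIR", "SI"),
                              time_mode = c("continuous", "discrete"),
                              n_bins = 15, seeds_per_bin = 5,
                              hub_fraction = 0.6, runs_per_seed = 100,
                              probe_runs = 40, x = 2, alpha = 2,
                              master_seed = 1) {
  cfg <- list(family = match.arg(family), n_networks = n_networks,
              n_nodes = n_nodes, degree_seq = degree_seq,
              weight_scheme = weight_scheme, model = match.arg(model),
              time_mode = match.arg(time_mode), n_bins = n_bins,
              seeds_per_bin = seeds_per_bin, hub_fraction = hub_fraction,
              runs_per_seed = runs_per_seed, probe_runs = probe_runs,
              x = x, alpha = alpha, master_seed = master_seed)
  if (cfg$family == "degseq" && is.null(cfg$degree_seq))
    stop("family 'degseq' requires degree_seq")
  if (cfg$n_bins < 1 || cfg$seeds_per_bin < 1)
    stop("n_bins and seeds_per_bin must be at least 1")
  structure(cfg, class = "experiment_config")
}

#' Run a family validation experiment
#'
#' For each replicate network: generate the network (and weights), score
#' every node (ExF, ExF^M, k-shell, eigenvector centrality), select binned
#' seeds, calibrate the transmissibility ratio (SIS/SIR), simulate outbreaks
#' from every seed, and correlate each metric with the per-seed outcome
#' (epidemic potential, or gamma-fit mean time to half coverage for SI).
#' Fully deterministic given `cfg$master_seed`. Networks whose calibration
#' or simulation fails are logged and skipped.
#'
#' @param cfg an [experiment_config()].
#' @param keep_runs logical; retain the per-run outcome table of every seed
#'   (needed e.g. to inspect extinct-run sizes).
#' @return an object of class `family_experiment`: a list with `per_seed`
#'   (data frame of seeds, metric values and outcomes), `per_network`
#'   (per-network correlation of each metric), `summary` (family mean and sd
#'   per metric), `runs` (if `keep_runs`), `attrition` (character log) and
#'   `config`.
#' @export
run_family_experiment <- function(cfg, keep_runs = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$master_seed)
  net_seeds <- sample.int(.Machine$integer.max, cfg$n_networks)
  metrics <- c("exf", "exf_weighted", "exfm", "kshell", "eigencent",
               "degree")
  per_seed <- list(); per_net <- list(); runs_log <- list()
  attrition <- character(0)
  outcome_kind <- if (cfg$model == "SI") "tthc" else "epo"

  for (i in seq_len(cfg$n_networks)) {
    set.seed(net_seeds[i])
    res <- tryCatch({
      net <- switch(cfg$family,
        pareto = chung_lu_pareto(cfg$n_nodes),
        degseq = degree_sequence_network(cfg$degree_seq, cfg$n_nodes))
      if (cfg$weight_scheme != "unit")
        net <- assign_weights(net, cfg$weight_scheme)
      scores <- node_score_table(net, x = cfg$x, alpha = cfg$alpha,
                                 exclude_hubs = TRUE,
                                 hub_fraction = cfg$hub_fraction)
      seeds <- select_seeds(scores, n_bins = cfg$n_bins,
                            seeds_per_bin = cfg$seeds_per_bin)
      beta <- NA_real_
      if (cfg$model != "SI") {
        beta <- calibrate_beta(net, seeds, model = cfg$model,
                               time_mode = cfg$time_mode,
                               probe_runs = cfg$probe_runs)
      }
      out <- lapply(seeds, function(s) {
        if (cfg$model == "SI") {
          o <- tthc_outcome(net, s, n_runs = cfg$runs_per_seed)
          list(outcome = o$tthc, runs = NULL)
        } else {
          runs <- simulate_outbreaks(net, s, model = cfg$model,
                                     time_mode = cfg$time_mode,
                                     beta = as.numeric(beta),
                                     n_runs = cfg$runs_per_seed)
          list(outcome = mean(runs$reached_half), runs = runs)
        }
      })
      srow <- scores[match(seeds, scores$node), , drop = FALSE]
      ps <- data.frame(network = i, seed = seeds,
                       degree = srow$degree, exf = srow$exf,
                       exf_weighted = if ("exf_weighted" %in% names(srow))
                         srow$exf_weighted else NA_real_,
                       exfm = srow$exfm, kshell = srow$kshell,
                       eigencent = srow$eigencent,
                       outcome = vapply(out, `[[`, 0, "outcome"),
                       beta = as.numeric(beta), stringsAsFactors = FALSE)
      rr <- NULL
      if (keep_runs && cfg$model != "SI") {
        rr <- do.call(rbind, lapply(seq_along(out), function(k)
          cbind(network = i, seed = seeds[k], out[[k]]$runs)))
      }
      list(ps = ps, rr = rr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      attrition <- c(attrition,
                     sprintf("network %d skipped: %s", i, conditionMessage(res)))
      next
    }
    per_seed[[length(per_seed) + 1L]] <- res$ps
    if (!is.null(res$rr)) runs_log[[length(runs_log) + 1L]] <- res$rr
    cors <- vapply(metrics, function(mcol) {
      v <- res$ps[[mcol]]
      if (all(is.na(v))) return(NA_real_)
      tryCatch(suppressWarnings(
        correlate(v, res$ps$outcome, outcome_kind = outcome_kind)),
        error = function(e) NA_real_)
    }, 0)
    per_net[[length(per_net) + 1L]] <-
      data.frame(network = i, metric = metrics, correlation = unname(cors),
                 stringsAsFactors = FALSE)
  }
  per_net <- if (length(per_net)) do.call(rbind, per_net) else
    data.frame(network = integer(0), metric = character(0),
               correlation = numeric(0))
  summ <- if (nrow(per_net)) {
    agg_m <- tapply(per_net$correlation, per_net$metric, mean, na.rm = TRUE)
    agg_s <- tapply(per_net$correlation, per_net$metric, stats::sd, na.rm = TRUE)
    data.frame(metric = names(agg_m), mean_correlation = as.numeric(agg_m),
               sd_correlation = as.numeric(agg_s), row.names = NULL,
               stringsAsFactors = FALSE)
  } else data.frame(metric = character(0), mean_correlation = numeric(0),
                    sd_correlation = numeric(0))
  structure(list(per_seed = if (length(per_seed)) do.call(rbind, per_seed)
                 else NULL,
                 per_network = per_net, summary = summ,
                 runs = if (keep_runs && length(runs_log))
                   do.call(rbind, runs_log) else NULL,
                 attrition = attrition, config = cfg,
                 outcome_kind = outcome_kind),
            class = "family_experiment")
}

#' @export
print.family_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Family experiment: %s, %d network(s), %s %s, outcome %s\n",
              cfg$family, length(unique(x$per_seed$network)), cfg$model,
              cfg$time_mode, x$outcome_kind))
  if (length(x$attrition))
    cat(length(x$attrition), "network(s) skipped (see $attrition)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
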