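#' Simulate stochastic outbreaks from a seed node
#'
#' Event-driven continuous-time and synchronous discrete-time SI/SIS/SIR
#' simulators. In continuous time the waiting time to the next transmission
#' is exponential with rate equal to the current (weight-)count of
#' infected-susceptible edges (scaled by `beta` for SIS/SIR), and each
#' infected node recovers at unit rate; the transmitting edge is chosen
#' proportionally to its weight among infected-susceptible edges. In discrete
#' time every infected-susceptible edge transmits independently each round
#' with probability `r` (per-edge `1 - (1-r)^w` on weighted graphs) and every
#' node infected at the start of a round recovers at its end (infectious
#' period of exactly one round).
#'
#' A run stops when the cumulative number of ever-infected nodes reaches
#' `half_target`, on extinction, or at `event_cap` transmission events
#' (continuous) / rounds (discrete).
#'
#' @param net a connected igraph graph (edge weights honoured when present).
#' @param seed seed node identifier or index.
#' @param model `"SI"`, `"SIS"` or `"SIR"`.
#' @param time_mode `"continuous"` or `"discrete"` (`"SI"` is
#'   continuous-time only).
#' @param beta transmissibility-to-recovery ratio (SIS/SIR, continuous).
#' @param r per-edge per-round transmission probability (discrete time);
#'   derive from `beta` with [beta_to_discrete()].
#' @param n_runs number of independent runs.
#' @param half_target epidemic size threshold; defaults to half the nodes
#'   (rounded up).
#' @param event_cap cap on transmissions/rounds, for very large networks.
#' @return a data frame with one row per run: `reached_half` (logical),
#'   `tthc` (time, or round count, at termination; the time to half coverage
#'   when `reached_half`), `max_ever_infected` (cumulative distinct nodes
#'   ever infected), `max_prevalence` (peak instantaneous infected count),
#'   `n_events`, and the bookkeeping columns `is_weight_final` /
#'   `is_weight_recount` (incrementally maintained vs recomputed
#'   infected-susceptible edge weight at termination; continuous time only).
#' @examples
#' g <- igraph::make_ring(10)
#' set.seed(1)
#' simulate_outbreaks(g, 1, model = "SI", n_runs = 3)
#' @export
simulate_outbreaks <- function(net, seed, model = c("SI", "SIS", "SIR"),
                               time_mode = c("continuous", "discrete"),
                               beta = NULL, r = NULL, n_runs = 1,
                               half_target = NULL, event_cap = Inf) {
  model <- match.arg(model)
  time_mode <- match.arg(time_mode)
  if (n_runs < 1) stop("n_runs must be at least 1")
  n <- igraph::vcount(net)
  if (is.null(half_target)) half_target <- ceiling(n / 2)
  s0 <- resolve_nodes(net, seed)
  if (length(s0) != 1) stop("exactly one seed node required")
  csr <- graph_csr(net)
  mcode <- match(model, c("SI", "SIS", "SIR")) - 1L

  if (model == "SI" || time_mode == "continuous") {
    if (model == "SI") {
      beta <- 1
    } else if (is.null(beta) || beta <= 0) {
      stop("beta must be positive for ", model, " simulations")
    }
    if (model == "SI" && time_mode == "discrete")
      stop("SI outbreaks are simulated in continuous time only")
    m <- .epi_ct_cpp(csr$ptr, csr$nbr, csr$wt, as.integer(s0 - 1L), mcode,
                     beta, as.integer(n_runs), as.integer(half_target),
                     as.double(event_cap))
  } else {
    if (is.null(r)) {
      if (is.null(beta)) stop("supply r, or beta to convert")
      r <- beta_to_discrete(beta)
    }
    if (r <= 0 || r >= 1)
      stop("r must lie in (0, 1); reduce beta if the conversion overflowed")
    m <- .epi_dt_cpp(csr$ptr, csr$nbr, csr$wt, as.integer(s0 - 1L), mcode,
                     r, as.integer(n_runs), as.integer(half_target),
                     as.double(event_cap))
  }
  data.frame(run = seq_len(n_runs),
             reached_half = m[, 1] > 0,
             tthc = m[, 2],
             max_ever_infected = as.integer(m[, 3]),
             max_prevalence = as.integer(m[, 7]),
             n_events = as.integer(m[, 4]),
             is_weight_final = m[, 5],
             is_weight_recount = m[, 6])
}

#' Convert a continuous-time transmissibility ratio to a per-round probability
#'
#' The default convention is `r = -log(1 - beta)`, the published conversion
#' used throughout the validation experiments; the textbook rate-to-
#' probability map `r = 1 - exp(-beta)` is selectable for comparison.
#'
#' @param beta transmissibility-to-recovery ratio; must satisfy `r < 1` under
#'   the chosen convention.
#' @param convention `"minus-log"` (default) or `"one-minus-exp"`.
#' @return the per-edge per-round transmission probability.
#' @examples
#' beta_to_discrete(0.5)                 # log(2)
#' beta_to_discrete(0.5, "one-minus-exp")
#' @export
beta_to_discrete <- function(beta, convention = c("minus-log", "one-minus-exp")) {
  convention <- match.arg(convention)
  if (any(beta < 0)) stop("beta must be nonnegative")
  r <- switch(convention,
              `minus-log` = -log(1 - beta),
              `one-minus-exp` = 1 - exp(-beta))
  if (any(!is.finite(r)) || any(r >= 1))
    stop("conversion yields r >= 1; reduce beta (needs beta < 1 - exp(-1) ",
         "under the minus-log convention)")
  r
}

#' Epidemic potential of a seed node
#'
#' The epidemic potential (EPo) is the fraction of stochastic SIS/SIR
#' outbreaks seeded at a node that infect at least half the network
#' (cumulative ever-infected count).
#'
#' @inheritParams simulate_outbreaks
#' @param n_runs number of outbreaks to simulate (100 in the reference
#'   protocol).
#' @return a list with `seed`, `epo`, `n_runs`, and `runs` (the run table).
#' @export
epidemic_potential <- function(net, seed, model = c("SIS", "SIR"),
                               time_mode = c("continuous", "discrete"),
                               beta = NULL, r = NULL, n_runs = 100,
                               half_target = NULL, event_cap = Inf) {
  model <- match.arg(model)
  if (n_runs < 1) stop("n_runs must be at least 1")
  runs <- simulate_outbreaks(net, seed, model = model, time_mode = time_mode,
                             beta = beta, r = r, n_runs = n_runs,
                             half_target = half_target, event_cap = event_cap)
  list(seed = node_ids(net)[resolve_nodes(net, seed)],
       epo = sum(runs$reached_half) / n_runs, n_runs = n_runs, runs = runs)
}

#' Time to half coverage of a seed node (SI outcome)
#'
#' Simulates `n_runs` continuous-time SI outbreaks and summarizes the
#' observed times to half coverage by the mean of a maximum-likelihood gamma
#' fit (falling back to the sample mean when the fit does not converge, e.g.
#' for degenerate samples).
#'
#' @inheritParams simulate_outbreaks
#' @return a list with `seed`, `tthc` (gamma-fit mean), `shape`, `rate`
#'   (NA on fallback), `n_runs` and the raw `times`.
#' @export
tthc_outcome <- function(net, seed, n_runs = 100, half_target = NULL,
                         event_cap = Inf) {
  runs <- simulate_outbreaks(net, seed, model = "SI",
                             time_mode = "continuous", n_runs = n_runs,
                             half_target = half_target, event_cap = event_cap)
  x <- runs$tthc[runs$reached_half]
  if (length(x) == 0)
    stop("no run reached half coverage; is the seed's component large enough?")
  fit <- gamma_fit_mean(x)
  list(seed = node_ids(net)[resolve_nodes(net, seed)], tthc = fit$mean,
       shape = fit$shape, rate = fit$rate, n_runs = n_runs, times = x)
}

gamma_fit_mean <- function(x) {
  if (length(x) < 2 || stats::var(x) == 0)
    return(list(mean = mean(x), shape = NA_real_, rate = NA_real_))
  fit <- tryCatch(suppressWarnings(MASS::fitdistr(x, "gamma")),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = mean(x), shape = NA_real_, rate = NA_real_))
  est <- fit$estimate
  list(mean = unname(est["shape"] / est["rate"]),
       shape = unname(est["shape"]), rate = unname(est["rate"]))
}

#' Calibrate the transmissibility ratio to the critical range
#'
#' Binary search on the multiple `c` in `beta = c / lambda` (with `lambda`
#' the largest adjacency eigenvalue) until at least `target_frac` of the
#' probe seeds have epidemic potential inside `epo_range`, the empirical
#' criterion for the critical range in which an epidemic is possible but not
#' guaranteed. Each probe evaluates the EPo of every seed with `probe_runs`
#' outbreaks.
#'
#' @inheritParams simulate_outbreaks
#' @param seeds probe seed nodes (names or indices); at least 10.
#' @param target_frac required fraction of seeds inside `epo_range`.
#' @param epo_range inclusive EPo acceptance interval.
#' @param probe_runs outbreaks per seed per probe.
#' @param multiple_range search interval for the multiple `c`.
#' @param max_iter maximum number of binary-search probes.
#' @param on_failure `"error"` to fail when the criterion is never met,
#'   `"best"` to return the best probe instead.
#' @return the calibrated `beta`, with attributes `multiple`, `lambda`,
#'   `frac_in_range`, and `trace` (a data frame of all probes).
#' @export
calibrate_beta <- function(net, seeds, model = c("SIS", "SIR"),
                           time_mode = c("continuous", "discrete"),
                           target_frac = 0.8, epo_range = c(0.05, 0.95),
                           probe_runs = 40, multiple_range = c(1 / 8, 32),
                           max_iter = 14, half_target = NULL,
                           on_failure = c("error", "best")) {
  model <- match.arg(model)
  time_mode <- match.arg(time_mode)
  on_failure <- match.arg(on_failure)
  sidx <- resolve_nodes(net, seeds)
  if (length(sidx) < 10) stop("at least 10 probe seeds are required")
  lam <- largest_eigenvalue(net)
  lo <- log(multiple_range[1]); hi <- log(multiple_range[2])
  # discrete time needs r = -log(1 - beta) < 1, i.e. beta < 1 - exp(-1)
  if (time_mode == "discrete")
    hi <- min(hi, log(0.99 * (1 - exp(-1)) * lam))
  probe <- function(beta) {
    epo <- vapply(sidx, function(s)
      epidemic_potential(net, s, model = model, time_mode = time_mode,
                         beta = beta, n_runs = probe_runs,
                         half_target = half_target)$epo, 0)
    c(f_in = mean(epo >= epo_range[1] & epo <= epo_range[2]),
      f_hi = mean(epo > epo_range[2]), f_lo = mean(epo < epo_range[1]))
  }
  trace <- data.frame()
  best <- list(frac = -1, beta = NA_real_, mult = NA_real_)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    beta <- exp(mid) / lam
    f <- probe(beta)
    trace <- rbind(trace, data.frame(iter = it, multiple = exp(mid),
                                     beta = beta, frac_in = f["f_in"],
                                     frac_high = f["f_hi"],
                                     frac_low = f["f_lo"],
                                     row.names = NULL))
    if (f["f_in"] > best$frac)
      best <- list(frac = f["f_in"], beta = beta, mult = exp(mid))
    if (f["f_in"] >= target_frac) {
      return(structure(beta, multiple = exp(mid), lambda = lam,
                       frac_in_range = unname(f["f_in"]), trace = trace))
    }
    if (f["f_hi"] > f["f_lo"]) hi <- mid else lo <- mid
  }
  if (on_failure == "best" && is.finite(best$beta)) {
    return(structure(best$beta, multiple = best$mult, lambda = lam,
                     frac_in_range = unname(best$frac), trace = trace))
  }
  stop(sprintf(paste0("calibrate_beta: criterion not met within %d probes; ",
                      "best fraction in range %.2f at beta = %.4g"),
               max_iter, best$frac, best$beta))
}
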