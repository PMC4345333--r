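# Desk-scale validation experiments shared by several acceptance checks.
# Computed once per test run and cached.

.exp_cache <- new.env(parent = emptyenv())

acc_ct_experiment <- function() {
  if (is.null(.exp_cache$ct)) {
    cfg <- experiment_config(family = "pareto", n_networks = 10,
                             n_nodes = 1000, model = "SIS",
                             time_mode = "continuous", seeds_per_bin = 2,
                             runs_per_seed = 50, master_seed = 101)
    .exp_cache$ct <- run_family_experiment(cfg, keep_runs = TRUE)
  }
  .exp_cache$ct
}

acc_dt_experiment <- function() {
  if (is.null(.exp_cache$dt)) {
    cfg <- experiment_config(family = "pareto", n_networks = 10,
                             n_nodes = 1000, weight_scheme = "uniform3",
                             model = "SIS", time_mode = "discrete",
                             seeds_per_bin = 2, runs_per_seed = 50,
                             master_seed = 102)
    .exp_cache$dt <- run_family_experiment(cfg)
  }
  .exp_cache$dt
}

mean_cor <- function(ex, metric) {
  ex$summary$mean_correlation[ex$summary$metric == metric]
}
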