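# Shared simulation runs, computed once per test session.

.run_cache <- new.env(parent = emptyenv())

# paper-scale default ensemble (Na+, 5 pN, 39 events) through the full
# pipeline; reused by the acceptance checks and profile invariants
cached_default_run <- function() {
  if (is.null(.run_cache$default)) {
    cfg <- sim_config(seed = 2026)
    ens <- simulate_ensemble(cfg, n_events = 39, n_controls = 3,
                             control_duration = 60)
    res <- run_pipeline(ens$traces, ens$controls,
                        analysis_config(seed = 2026))
    .run_cache$default <- list(cfg = cfg, ens = ens, res = res)
  }
  .run_cache$default
}

# small ensemble for cheaper structural tests
cached_small_run <- function() {
  if (is.null(.run_cache$small)) {
    cfg <- sim_config(seed = 77)
    ens <- simulate_ensemble(cfg, n_events = 5, n_controls = 2,
                             control_duration = 30)
    res <- run_pipeline(ens$traces, ens$controls, analysis_config(seed = 77))
    .run_cache$small <- list(cfg = cfg, ens = ens, res = res)
  }
  .run_cache$small
}
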