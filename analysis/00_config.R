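# Shared settings for the numbered analysis drivers.  Each driver is a
# thin narrative over the package functions; all computation lives in the
# foremort package so the same code paths are exercised by the tests.

suppressMessages({
  library(foremort)
  library(data.table)
})

ANALYSIS_SEED <- 20260925L
ANALYSIS_CFG <- pipeline_config(
  n_counties = 100, n_states = 10, n_wfos = 12,
  years = 2005:2012, n_experts = 11, n_ci_draws = 200L)

dir.create("results", showWarnings = FALSE)

# deterministic per-stage seeds, mirroring run_pipeline()
stage_seed <- function(k) ANALYSIS_SEED + k
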