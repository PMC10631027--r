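# The end-to-end synthetic study is expensive (minutes), so it is built once
# and shared by the acceptance tests that probe different aspects of it.
.acceptance_env <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (!is.null(.acceptance_env$run)) return(.acceptance_env$run)
  cohort <- synth_cohort(synth_config(seed = 11))
  res <- run_pipeline(cohort, seed = 11, min_retained = 50)
  .acceptance_env$run <- list(cohort = cohort, res = res)
  .acceptance_env$run
}
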