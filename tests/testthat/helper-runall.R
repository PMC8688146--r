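# The full-cohort pipeline run is shared between the end-to-end power check
# and the reproducibility check; compute it once per test session.
.runall_cache <- new.env(parent = emptyenv())

full_run <- function(which = c("first", "second")) {
  which <- match.arg(which)
  key <- paste0("run_", which)
  if (is.null(.runall_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("fdgkin_runall_", which))
    run <- run_all(default_run_config(seed = 1L), out_dir = dir)
    .runall_cache[[key]] <- list(run = run, dir = dir)
  }
  .runall_cache[[key]]
}
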