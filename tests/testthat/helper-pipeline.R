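# One default-conditions pipeline run, computed once and shared by the
# heavier end-to-end tests.
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline_run <- function() {
  if (is.null(.pipeline_cache$run)) {
    dir <- file.path(tempdir(), "epipersist-default-run")
    .pipeline_cache$run <- suppressMessages(
      run_pipeline(sim_config(42), dir))
  }
  .pipeline_cache$run
}

# a reduced genome for tests that need speed rather than power
small_config <- function(seed = 7) {
  sim_config(seed,
             layout = list(n_chrom = 1, chrom_length = 4e5),
             rrbs = list(n_dmr = 60),
             features = list(n_tss = 60, n_cpg_island = 50, n_enhancer = 40,
                             n_repeat = 80, n_gene_body = 40, n_variant = 40),
             motifs = list(n_control_seqs = 200))
}
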