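# Small shared end-to-end fixture, built once per test run: a 120-kbp
# genome, four scaffolds carrying two middle insertions, one end
# insertion and one deletion, 40x reads. No SVs, no misjoins (those are
# exercised at full scale in the acceptance suite).
.fixture_env <- new.env(parent = emptyenv())

small_scenario <- function() {
  if (is.null(.fixture_env$sc)) {
    set.seed(424)
    .fixture_env$sc <- simulate_scenario(
      seed = 424, genome_len = 120000L, n_misjoin = 0L, n_ins_mid = 2L,
      n_ins_end = 1L, n_del = 1L, svs = NULL, depth = 40)
  }
  .fixture_env$sc
}

small_pipeline_result <- function() {
  if (is.null(.fixture_env$res)) {
    sc <- small_scenario()
    set.seed(77)
    .fixture_env$res <- run_misasm(
      sc$scaffolds, sc$reference,
      reads = list(read1 = sc$read1, read2 = sc$read2),
      insert_mu = sc$insert_mu, insert_sd = sc$insert_sd,
      truth = sc$truth)
  }
  .fixture_env$res
}
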