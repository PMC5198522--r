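# Shared builders for small in-code fixtures.

balanced_design <- function(r = 2L) {
  experiment_design(
    sample_id = c(paste0("rna_c", 1:r), paste0("rna_t", 1:r),
                  paste0("rf_c", 1:r), paste0("rf_t", 1:r)),
    protocol = rep(c("RNA", "RF"), each = 2L * r),
    condition = rep(rep(c("control", "treatment"), each = r), 2L))
}

# counts laid out to match balanced_design(r) column order
joined_from_matrix <- function(counts, r = 2L, gene_ids = NULL) {
  d <- balanced_design(r)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(counts)))
  rna <- count_table(gene_ids, d$sample_id[1:(2 * r)],
                     counts[, 1:(2 * r), drop = FALSE])
  ribo <- count_table(gene_ids, d$sample_id[(2 * r + 1):(4 * r)],
                      counts[, (2 * r + 1):(4 * r), drop = FALSE])
  join_datasets(rna, ribo, d)
}

sim_joined <- function(...) {
  sim <- simulate_dataset(sim_config(...))
  list(sim = sim, joined = join_datasets(sim$rna, sim$ribo, sim$design))
}

# Heavy shared datasets for the acceptance checks, computed once per
# session and reused across blocks.
.accept_cache <- new.env(parent = emptyenv())

accept_null_run <- function() {
  if (is.null(.accept_cache$null)) {
    sim <- simulate_dataset(sim_config(
      n_genes = 2000L, reps = 3L, kappa_rna = 0.05, kappa_rf = 0.2,
      fraction_affected = 0, seed = 1L))
    joined <- join_datasets(sim$rna, sim$ribo, sim$design)
    res <- suppressWarnings(run_pipeline(joined, mode = "SEPARATE"))
    .accept_cache$null <- list(sim = sim, joined = joined, res = res)
  }
  .accept_cache$null
}

accept_effect_run <- function() {
  if (is.null(.accept_cache$effect)) {
    sim <- simulate_dataset(sim_config(
      n_genes = 2000L, reps = 5L, fraction_affected = 0.1,
      effect_log_fc = log(4), seed = 11L))
    joined <- join_datasets(sim$rna, sim$ribo, sim$design)
    res <- suppressWarnings(run_pipeline(joined, mode = "SEPARATE"))
    .accept_cache$effect <- list(sim = sim, joined = joined, res = res)
  }
  .accept_cache$effect
}
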