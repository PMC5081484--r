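library(data.table)

## Small configs used across test files.  `tiny_config()` is scaled for
## speed; `study_config()` is the stated full-size world (55 genes,
## 9 + 11 samples, 3 replicates) used by the acceptance tests.

tiny_config <- function(...) {
  defaults <- list(n_genes = 8L, n_cell_lines = 3L, n_tissues = 3L,
                   n_replicates = 2L,
                   peptide_count_distribution = c(`1` = 4L, `2` = 3L,
                                                  `3` = 1L),
                   missing_fraction = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

study_config <- function(...) {
  do.call(sim_config, utils::modifyList(list(seed = 20L), list(...)))
}

noise_free <- function(cfg_fun = tiny_config, ...) {
  cfg_fun(copy_noise_sd_log10 = 0, fragment_noise_sd_log10 = 0,
          missing_fraction = 0, ...)
}

make_bundle <- function(cfg) {
  truth <- generate_truth(cfg)
  bundle <- generate_measurements(truth, cfg)
  list(truth = truth, bundle = bundle, cfg = cfg)
}

## Run quantification through copy numbers on a bundle.
pipeline_copies <- function(bundle, mode = "calibrated",
                            policy = "median_of_fragments",
                            rollup = "peptides_first") {
  pr <- peptide_ratios(bundle$transitions, policy = policy)
  filt <- filter_quantifiable(pr, bundle$samples$sample_id)
  ha <- histone_amounts(filt$ratios, bundle$spikes)
  cc <- cells_from_histones(ha, cell_count_model(mode = mode),
                            bundle$samples)
  pc <- peptide_copies(filt$ratios[!gene_id %in% histone_gene_ids()],
                       bundle$spikes, cc)
  protein_copies(pc, rollup = rollup)
}

## Hand-built 2-fragment transition table for contract tests.
toy_transitions <- function() {
  data.table(
    sample_id = "S1", replicate_id = "r1", gene_id = "G1",
    peptide_seq = "PEPA",
    fragment_ion = rep(c("y4", "y5"), each = 2),
    label = rep(c("light", "heavy"), 2),
    area = c(100, 100, 250, 100)
  )
}

## Independent brute-force median: sort, middle (or mean of middle two).
oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}
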