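## Synthetic measurement bundles with known ground truth.
##
## The generator emulates a multiplexed PRM study: a panel of genes
## measured across cell-line and tissue samples in replicate, each gene
## covered by 1-5 proteotypic peptides with 3-6 fragment ions, heavy
## spike-in standards at fixed fmol amounts, and four core-histone
## anchors per replicate that carry the cell-count signal.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a 55-gene panel measured across 9 cell lines and
#' 11 tissues in triplicate, with gene-specific RNA-to-protein ratios
#' spanning roughly 200 to 220,000 protein copies per TPM unit, and the
#' peptide-coverage distribution of a typical multiplexed assay
#' (24 genes with one peptide, 13 with two, 11 with three, 5 with four,
#' 2 with five).
#'
#' @param n_genes number of non-histone target genes
#' @param n_cell_lines,n_tissues number of samples of each class
#' @param n_replicates technical replicates per sample
#' @param rtp_log10_range log10 range of true RTP factors (copies/TPM),
#'   drawn log-uniform per gene
#' @param tpm_gene_mean_log10_range log10 range of per-gene TPM location
#' @param tpm_sample_sd_log10 sd (log10) of per-sample TPM around the
#'   gene location
#' @param copy_noise_sd_log10 sd (log10) of multiplicative biological +
#'   preparation noise on protein copies
#' @param fragment_noise_sd_log10 sd (log10) of multiplicative
#'   instrument noise on each fragment area (replicate-to-replicate
#'   variability is folded in here)
#' @param peptide_count_distribution named integer vector mapping
#'   peptides-per-gene to number of genes; must sum to `n_genes`.  When
#'   `n_genes` differs from 55 and no distribution is given, every gene
#'   gets two peptides.
#' @param fragments_per_peptide inclusive integer range of fragment ions
#'   per peptide
#' @param missing_fraction fraction of non-histone gene-sample pairs
#'   whose endogenous (light) signal is removed entirely
#' @param cells_per_cellline_sample counted cells in each processed
#'   cell-line aliquot
#' @param tissue_cell_range_fold fold range of cells per fixed lysate
#'   mass across tissues (spleen/tonsil vs heart-like spread)
#' @param tissue_lysate_mass_mg processed lysate mass per tissue aliquot
#' @param histones_per_cell copies of each core histone per 2N cell
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed)
#' @return a validated `sim_config` object (a list)
#' @export
sim_config <- function(n_genes = 55L,
                       n_cell_lines = 9L,
                       n_tissues = 11L,
                       n_replicates = 3L,
                       rtp_log10_range = c(log10(200), log10(220000)),
                       tpm_gene_mean_log10_range = c(0, 3),
                       tpm_sample_sd_log10 = 0.4,
                       copy_noise_sd_log10 = 0.12,
                       fragment_noise_sd_log10 = 0.05,
                       peptide_count_distribution = NULL,
                       fragments_per_peptide = c(3L, 6L),
                       missing_fraction = 0.02,
                       cells_per_cellline_sample = 1e6,
                       tissue_cell_range_fold = 30,
                       tissue_lysate_mass_mg = 0.6,
                       histones_per_cell = 6.4e7,
                       seed = 1L) {
  if (is.null(peptide_count_distribution)) {
    peptide_count_distribution <- if (n_genes == 55L) {
      c(`1` = 24L, `2` = 13L, `3` = 11L, `4` = 5L, `5` = 2L)
    } else {
      stats::setNames(as.integer(n_genes), "2")
    }
  }
  ## accept a named list (e.g. from a JSON config)
  if (is.list(peptide_count_distribution))
    peptide_count_distribution <- unlist(peptide_count_distribution)
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_cell_lines = as.integer(n_cell_lines),
    n_tissues = as.integer(n_tissues),
    n_replicates = as.integer(n_replicates),
    rtp_log10_range = as.numeric(rtp_log10_range),
    tpm_gene_mean_log10_range = as.numeric(tpm_gene_mean_log10_range),
    tpm_sample_sd_log10 = tpm_sample_sd_log10,
    copy_noise_sd_log10 = copy_noise_sd_log10,
    fragment_noise_sd_log10 = fragment_noise_sd_log10,
    peptide_count_distribution = peptide_count_distribution,
    fragments_per_peptide = as.integer(fragments_per_peptide),
    missing_fraction = missing_fraction,
    cells_per_cellline_sample = cells_per_cellline_sample,
    tissue_cell_range_fold = tissue_cell_range_fold,
    tissue_lysate_mass_mg = tissue_lysate_mass_mg,
    histones_per_cell = histones_per_cell,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  }
  for (f in c("n_genes", "n_cell_lines", "n_tissues", "n_replicates")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      bad(f, "must be a positive count")
  }
  for (f in c("tpm_sample_sd_log10", "copy_noise_sd_log10",
              "fragment_noise_sd_log10")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      bad(f, "noise sd must be >= 0")
  }
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    bad("missing_fraction", "must lie in [0, 1)")
  pcd <- cfg$peptide_count_distribution
  if (is.null(names(pcd)) || any(is.na(as.integer(names(pcd)))))
    bad("peptide_count_distribution", "names must be peptide counts")
  if (sum(pcd) != cfg$n_genes)
    bad("peptide_count_distribution",
        sprintf("sums to %d, not n_genes = %d", sum(pcd), cfg$n_genes))
  if (length(cfg$fragments_per_peptide) != 2L ||
      cfg$fragments_per_peptide[1] < 1L ||
      diff(cfg$fragments_per_peptide) < 0)
    bad("fragments_per_peptide", "must be an increasing range >= 1")
  if (diff(cfg$rtp_log10_range) < 0)
    bad("rtp_log10_range", "must be an increasing interval")
  for (f in c("cells_per_cellline_sample", "tissue_cell_range_fold",
              "tissue_lysate_mass_mg", "histones_per_cell")) {
    if (cfg[[f]] <= 0) bad(f, "must be > 0")
  }
  invisible(cfg)
}

#' Names of the four histone anchor pseudo-genes
#' @return character vector of length 4
#' @export
histone_gene_ids <- function() c("H2A", "H2B", "H3", "H4")

#' Draw ground-truth parameters for a synthetic study
#'
#' True RTP factors are log-uniform over `rtp_log10_range`; per-gene TPM
#' locations are log-uniform; per-sample TPM is log-normal around the
#' location; true copies per cell are `RTP * TPM` times log-normal noise
#' with sd `copy_noise_sd_log10` (with sd 0 the product is exact).
#' Cell-line aliquots contain exactly the counted cells; tissue cell
#' content per fixed lysate mass is log-uniform over a
#' `tissue_cell_range_fold` span centred on the cell-line count.
#' Spike amounts are set so that the heavy standard is roughly 1:1 with
#' the median endogenous level, as a real mastermix would be titrated.
#'
#' @param config a [sim_config()]
#' @return an `rtp_truth` list: `genes`, `samples`, `peptides`,
#'   `true_rtp`, `true_tpm`, `true_copies`, `true_cells`, `spikes`
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, "truth"))

  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  samples <- data.table(
    sample_id = c(sprintf("CL%02d", seq_len(config$n_cell_lines)),
                  sprintf("TS%02d", seq_len(config$n_tissues))),
    sample_class = c(rep("cell_line", config$n_cell_lines),
                     rep("tissue", config$n_tissues))
  )
  samples[, counted_cells := ifelse(sample_class == "cell_line",
                                    config$cells_per_cellline_sample, NA_real_)]
  samples[, lysate_mass_mg := ifelse(sample_class == "tissue",
                                     config$tissue_lysate_mass_mg, NA_real_)]
  reps <- sprintf("r%d", seq_len(config$n_replicates))

  ## peptide coverage: shuffle the stated peptides-per-gene distribution
  pcd <- config$peptide_count_distribution
  per_gene <- sample(rep(as.integer(names(pcd)), times = pcd))
  peptides <- rbindlist(lapply(seq_along(genes), function(i) {
    k <- per_gene[i]
    data.table(
      gene_id = genes[i],
      peptide_seq = sprintf("%sPEP%02d", genes[i], seq_len(k)),
      n_fragments = sample(seq(config$fragments_per_peptide[1],
                               config$fragments_per_peptide[2]), k,
                           replace = TRUE)
    )
  }))
  ## histone anchors: two peptides each, never missing
  hist_pep <- CJ(gene_id = histone_gene_ids(), idx = 1:2)
  hist_pep <- data.table(
    gene_id = hist_pep$gene_id,
    peptide_seq = sprintf("%sPEP%02d", hist_pep$gene_id, hist_pep$idx),
    n_fragments = sample(seq(config$fragments_per_peptide[1],
                             config$fragments_per_peptide[2]),
                         nrow(hist_pep), replace = TRUE)
  )
  peptides <- rbind(peptides, hist_pep)

  true_rtp <- stats::setNames(
    10 ^ runif(config$n_genes, config$rtp_log10_range[1],
               config$rtp_log10_range[2]), genes)
  mu <- runif(config$n_genes, config$tpm_gene_mean_log10_range[1],
              config$tpm_gene_mean_log10_range[2])
  ns <- nrow(samples)
  true_tpm <- 10 ^ (matrix(mu, config$n_genes, ns) +
                    matrix(rnorm(config$n_genes * ns, 0,
                                 config$tpm_sample_sd_log10),
                           config$n_genes, ns))
  dimnames(true_tpm) <- list(genes, samples$sample_id)
  noise <- matrix(rnorm(config$n_genes * ns, 0, config$copy_noise_sd_log10),
                  config$n_genes, ns)
  true_copies <- true_rtp * true_tpm * 10 ^ noise
  dimnames(true_copies) <- dimnames(true_tpm)

  ## cells per (sample, replicate): exact for counted cell lines,
  ## log-uniform spread for tissues, constant across replicates
  fold <- config$tissue_cell_range_fold
  tissue_cells <- config$cells_per_cellline_sample *
    10 ^ runif(config$n_tissues, -log10(fold) / 2, log10(fold) / 2)
  sample_cells <- c(rep(config$cells_per_cellline_sample,
                        config$n_cell_lines), tissue_cells)
  true_cells <- CJ(sample_id = samples$sample_id, replicate_id = reps,
                   sorted = FALSE)
  true_cells[, cells := rep(sample_cells, each = config$n_replicates)]

  ## spike titration: ~1:1 with the median endogenous amount at the
  ## reference (cell-line) cell count; one mastermix for all samples
  ref_cells <- config$cells_per_cellline_sample
  med_copies <- apply(true_copies, 1, median)
  spike_per_gene <- c(
    med_copies * ref_cells / .MOL_PER_FMOL,
    stats::setNames(rep(config$histones_per_cell * ref_cells / .MOL_PER_FMOL, 4),
                    histone_gene_ids()))
  spikes <- CJ(peptide_seq = peptides$peptide_seq,
               sample_id = samples$sample_id, sorted = FALSE)
  spikes <- merge(spikes, peptides[, .(gene_id, peptide_seq)],
                  by = "peptide_seq")
  spikes[, heavy_amount := spike_per_gene[gene_id]]
  setcolorder(spikes, c("gene_id", "peptide_seq", "sample_id",
                        "heavy_amount"))
  setkey(spikes, gene_id, peptide_seq, sample_id)

  structure(list(
    genes = genes, samples = samples, replicates = reps,
    peptides = peptides, true_rtp = true_rtp, true_tpm = true_tpm,
    true_copies = true_copies, true_cells = true_cells,
    spikes = spikes, config = config
  ), class = "rtp_truth")
}

#' Emit a measurement bundle from ground truth
#'
#' For every (gene, peptide, fragment, sample, replicate): the heavy
#' fragment area is spike amount times a per-fragment response factor;
#' the light area is the heavy area times the true light/heavy ratio
#' (copies-per-cell times cells over spiked molecules) times
#' multiplicative log-normal instrument noise.  Histone anchors carry
#' the cell-count signal (`cells * histones_per_cell`) and are never
#' blanked.  A `missing_fraction` of non-histone gene-sample pairs has
#' all light rows removed across replicates, emulating genes whose
#' endogenous peptides could not be quantified in a sample.
#'
#' @param truth an `rtp_truth` from [generate_truth()]
#' @param config the same [sim_config()]
#' @return an `rtp_bundle` list: `transitions`, `spikes`, `samples`,
#'   `tpm`, `missing` (data.table of blanked gene-sample pairs)
#' @export
generate_measurements <- function(truth, config) {
  stopifnot(inherits(truth, "rtp_truth"), inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, "measurements"))

  peptides <- truth$peptides
  frag <- peptides[, .(fragment_ion = sprintf("y%d", 3 + seq_len(n_fragments))),
                   by = .(gene_id, peptide_seq)]
  ## per-fragment instrument response (area units per fmol on column)
  frag[, response := 1e5 * 10 ^ runif(.N, -0.3, 0.3)]

  cells <- truth$true_cells
  grid <- frag[CJ(peptide_seq = unique(frag$peptide_seq),
                  sample_id = truth$samples$sample_id,
                  replicate_id = truth$replicates, sorted = FALSE),
               on = "peptide_seq", allow.cartesian = TRUE]
  grid <- merge(grid, truth$spikes,
                by = c("gene_id", "peptide_seq", "sample_id"))
  grid <- merge(grid, cells, by = c("sample_id", "replicate_id"))

  hist_ids <- histone_gene_ids()
  per_cell <- truth$true_copies  # genes x samples
  grid[, copies_pc := NA_real_]
  grid[gene_id %in% hist_ids, copies_pc := config$histones_per_cell]
  grid[!gene_id %in% hist_ids,
       copies_pc := per_cell[cbind(gene_id, sample_id)]]
  grid[, true_ratio := copies_pc * cells / (heavy_amount * .MOL_PER_FMOL)]
  grid[, heavy_area := heavy_amount * response]
  grid[, light_area := heavy_area * true_ratio *
         10 ^ rnorm(.N, 0, config$fragment_noise_sd_log10)]

  ## gene-sample dropouts (all peptides, all replicates; histones exempt)
  pairs <- CJ(gene_id = truth$genes, sample_id = truth$samples$sample_id,
              sorted = FALSE)
  pairs[, miss := runif(.N) < config$missing_fraction]
  missing <- pairs[miss == TRUE, .(gene_id, sample_id)]

  long <- rbind(
    grid[, .(sample_id, replicate_id, gene_id, peptide_seq, fragment_ion,
             label = "light", area = light_area)],
    grid[, .(sample_id, replicate_id, gene_id, peptide_seq, fragment_ion,
             label = "heavy", area = heavy_area)]
  )
  if (nrow(missing))
    long <- long[!(label == "light" &
                     paste(gene_id, sample_id) %in%
                     missing[, paste(gene_id, sample_id)])]
  setkey(long, sample_id, replicate_id, gene_id, peptide_seq,
         fragment_ion, label)

  structure(list(
    transitions = long,
    spikes = copy(truth$spikes),
    samples = data.table(
      sample_id = truth$samples$sample_id,
      sample_class = truth$samples$sample_class,
      replicate_ids = rep(list(truth$replicates), nrow(truth$samples)),
      counted_cells = truth$samples$counted_cells,
      lysate_mass_mg = truth$samples$lysate_mass_mg
    ),
    tpm = truth$true_tpm,
    missing = missing
  ), class = "rtp_bundle")
}

#' Write a measurement bundle to disk
#'
#' Emits the four tabular interfaces consumed by the readers:
#' `transition_report.csv`, `spike_table.tsv`, `sample_sheet.tsv`,
#' `tpm_matrix.tsv`.  Round-trips losslessly through [read_bundle()].
#'
#' @param bundle an `rtp_bundle`
#' @param directory output directory (created if absent)
#' @return named character vector of the four file paths, invisibly
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "rtp_bundle"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  paths <- c(
    transitions = file.path(directory, "transition_report.csv"),
    spikes = file.path(directory, "spike_table.tsv"),
    samples = file.path(directory, "sample_sheet.tsv"),
    tpm = file.path(directory, "tpm_matrix.tsv")
  )
  write_transition_report(bundle$transitions, paths["transitions"])
  write_spike_table(bundle$spikes, paths["spikes"])
  write_sample_sheet(bundle$samples, paths["samples"])
  write_tpm_matrix(bundle$tpm, paths["tpm"])
  invisible(paths)
}

#' Read a bundle directory written by [write_bundle()]
#' @param directory directory holding the four tables
#' @return an `rtp_bundle` (without a `missing` log)
#' @export
read_bundle <- function(directory) {
  b <- structure(list(
    transitions = read_transition_report(
      file.path(directory, "transition_report.csv")),
    spikes = read_spike_table(file.path(directory, "spike_table.tsv")),
    samples = read_sample_sheet(file.path(directory, "sample_sheet.tsv")),
    tpm = read_tpm_matrix(file.path(directory, "tpm_matrix.tsv")),
    missing = NULL
  ), class = "rtp_bundle")
  validate_bundle(b)
  b
}
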