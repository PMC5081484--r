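## One-call orchestration: simulate (optional) -> quantify ->
## cell-count -> copy-number -> rtp -> cv, with a machine-readable run
## manifest.  The run is a pure function of (inputs, config, seed).

#' Assemble a pipeline configuration
#'
#' Exactly one of `input` (named paths: transitions, spikes, samples,
#' tpm) or `simulate` (arguments for [sim_config()]) must be given.
#'
#' @param input named list/vector of the four input paths
#' @param simulate named list of [sim_config()] arguments
#' @param out_dir output directory
#' @param policy fragment-to-peptide combine policy (see
#'   [peptide_ratios()])
#' @param min_fragments minimum usable fragments per peptide
#' @param drop quantifiability filter scope (see
#'   [filter_quantifiable()])
#' @param cell_mode `"calibrated"` or `"constant"` (see
#'   [cell_count_model()])
#' @param histones_per_cell histone-ruler constant
#' @param rollup copy-number rollup order (see [protein_copies()])
#' @param cv_sizes training sizes for [cv_curve()] (NULL = all), or
#'   `FALSE` to skip the CV stage
#' @param cv_predictions_per_size prediction events per size
#' @param seed top-level seed fanned out to named substreams
#' @return a `run_config` list
#' @export
run_config <- function(input = NULL, simulate = NULL, out_dir,
                       policy = "median_of_fragments",
                       min_fragments = 1L, drop = "global",
                       cell_mode = "calibrated",
                       histones_per_cell = 6.4e7,
                       rollup = "peptides_first",
                       cv_sizes = NULL,
                       cv_predictions_per_size = 500L,
                       seed = 1L) {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' and 'simulate' must be given",
         call. = FALSE)
  if (!is.null(input)) {
    need <- c("transitions", "spikes", "samples", "tpm")
    miss <- setdiff(need, names(input))
    if (length(miss))
      stop("input is missing path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    absent <- unlist(input[need])[!file.exists(unlist(input[need]))]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
  }
  structure(list(input = input, simulate = simulate, out_dir = out_dir,
                 policy = policy, min_fragments = min_fragments,
                 drop = drop, cell_mode = cell_mode,
                 histones_per_cell = histones_per_cell, rollup = rollup,
                 cv_sizes = cv_sizes,
                 cv_predictions_per_size = cv_predictions_per_size,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from a JSON file
#' @param path JSON file whose keys are [run_config()] arguments
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Stages: (optional) simulate and write a bundle; read and
#' cross-validate the four tables; roll up peptide ratios; apply the
#' quantifiability filter; histone-ruler cell counts; copies per cell;
#' RTP table, per-gene correlations and leave-one-out predictions;
#' (optional) CV robustness curve.  All result tables are written under
#' `out_dir` with a provenance comment header; counts at every filter
#' go into the manifest (`manifest.json`).
#'
#' @param config a `run_config` (or a path to a JSON config)
#' @return invisible list of in-memory results: `bundle`, `ratios`,
#'   `exclusions`, `cells`, `copies`, `rtp_table`, `gene_cor`, `loo`,
#'   `cv`, `manifest`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cfg_hash <- substr(jsonlite::base64_enc(serialize(
    config[setdiff(names(config), "out_dir")], NULL)), 1, 12)
  meta <- c(config_hash = cfg_hash, seed = config$seed)
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   version = as.character(utils::packageVersion("rtpquant")))

  bundle <- stage("input", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- NULL  # the pipeline seed is authoritative
      sc <- do.call(sim_config, c(sim_args,
                                  list(seed = sub_seed(config$seed,
                                                       "simulate"))))
      truth <- generate_truth(sc)
      b <- generate_measurements(truth, sc)
      write_bundle(b, file.path(config$out_dir, "bundle"))
      attr(b, "truth") <- truth
      b
    } else {
      structure(list(
        transitions = read_transition_report(config$input$transitions),
        spikes = read_spike_table(config$input$spikes),
        samples = read_sample_sheet(config$input$samples),
        tpm = read_tpm_matrix(config$input$tpm)
      ), class = "rtp_bundle")
    }
  })
  stage("validate", validate_bundle(bundle))
  manifest$n_transitions <- nrow(bundle$transitions)
  manifest$n_samples <- nrow(bundle$samples)

  pr <- stage("quantify", peptide_ratios(bundle$transitions,
                                         policy = config$policy,
                                         min_fragments = config$min_fragments))
  manifest$n_peptide_ratios <- nrow(pr)

  filt <- stage("filter", filter_quantifiable(
    pr, bundle$samples$sample_id, drop = config$drop))
  manifest$genes_excluded <- unique(filt$exclusions$gene_id)
  write_result_table(filt$exclusions,
                     file.path(config$out_dir, "exclusions.tsv"), meta)

  cells <- stage("cell-count", {
    model <- cell_count_model(histones_per_cell = config$histones_per_cell,
                              mode = config$cell_mode)
    ha <- histone_amounts(filt$ratios, bundle$spikes)
    cc <- cells_from_histones(ha, model, bundle$samples)
    normalization_factors(cc, bundle$samples)
  })
  manifest$calibration_factor <-
    attr(cells, "model", exact = TRUE)$calibration_factor %||% 1
  write_result_table(cells, file.path(config$out_dir, "cell_counts.tsv"),
                     meta)

  copies <- stage("copy-number", {
    target <- filt$ratios[!gene_id %in% histone_gene_ids()]
    pc <- peptide_copies(target, bundle$spikes, cells)
    protein_copies(pc, rollup = config$rollup)
  })
  manifest$n_genes_quantified <- nrow(copies)
  write_result_table(
    data.table(gene_id = rownames(copies), as.data.table(copies)),
    file.path(config$out_dir, "copy_numbers.tsv"), meta)

  rtpm <- stage("rtp", rtp_ratios(copies, bundle$tpm))
  manifest$rtp_pairs_dropped <- as.list(attr(rtpm, "dropped"))
  rtab <- stage("rtp", gene_rtp(rtpm))
  write_result_table(rtab, file.path(config$out_dir, "rtp_table.tsv"),
                     meta)
  gcor <- stage("rtp", gene_correlations(copies, bundle$tpm))
  write_result_table(gcor,
                     file.path(config$out_dir, "gene_correlations.tsv"),
                     meta)
  loo <- stage("predict", predict_loo(copies, bundle$tpm))
  write_result_table(loo$sample_correlations,
                     file.path(config$out_dir, "sample_correlations.tsv"),
                     meta)
  write_result_table(
    data.table(gene_id = rownames(loo$predicted),
               as.data.table(loo$predicted)),
    file.path(config$out_dir, "predictions.tsv"), meta)
  manifest$loo_summary <- as.list(loo$summary)

  cv <- NULL
  if (!identical(config$cv_sizes, FALSE)) {
    cv <- stage("cv", cv_curve(
      copies, bundle$tpm, sizes = config$cv_sizes,
      n_predictions_per_size = config$cv_predictions_per_size,
      seed = sub_seed(config$seed, "cv-stage")))
    cvs <- summarize_cv(cv)
    write_result_table(cvs, file.path(config$out_dir, "cv_curve.tsv"),
                       meta)
    manifest$cv_median_by_size <- stats::setNames(cvs$median,
                                                  cvs$size)
  }

  ## truth-recovery diagnostics when simulating
  truth <- attr(bundle, "truth", exact = TRUE)
  if (!is.null(truth)) {
    shared <- intersect(rtab$gene_id, names(truth$true_rtp))
    err <- abs(log10(stats::setNames(rtab$rtp_central,
                                     rtab$gene_id)[shared] /
                       truth$true_rtp[shared]))
    manifest$rtp_recovery <- list(
      n_genes = length(shared),
      median_abs_log10_error = median(err),
      max_abs_log10_error = max(err))
  }

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(bundle = bundle, ratios = filt$ratios,
                 exclusions = filt$exclusions, cells = cells,
                 copies = copies, rtp_table = rtab, gene_cor = gcor,
                 loo = loo, cv = cv, manifest = manifest))
}
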