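## Histone-ruler cell counting.
##
## The four core histones (H2A, H2B, H3, H4) are deposited on DNA at a
## density fixed by the nucleosome repeat, so their molar amount in a
## lysate is proportional to the DNA content and hence to the number of
## (2N) cells.  Quantifying them with heavy spike-in standards gives an
## effective cell number for samples where direct counting is
## impossible (tissue lysates), and a per-replicate normalization
## anchor that cancels pipetting and load differences.

#' Cell-count model
#'
#' `histones_per_cell` defaults to 6.4e7: a diploid genome of ~6.4e9 bp
#' at one nucleosome per ~200 bp and 2 copies of each core histone per
#' nucleosome.  In `calibrated` mode (default when counted cell lines
#' are available) the constant cancels: a multiplicative factor is
#' fitted so the histone-derived estimates match the counted cells, and
#' the same factor is applied to all samples.  `dna_pg_per_cell` is the
#' DNA mass of a 2N human cell used by [cells_from_dna()].
#'
#' @param dna_pg_per_cell pg DNA per 2N cell (default 3.59)
#' @param histones_per_cell copies of each core histone per 2N cell
#' @param mode `"calibrated"` or `"constant"`
#' @return a `cell_count_model` list
#' @export
cell_count_model <- function(dna_pg_per_cell = 3.59,
                             histones_per_cell = 6.4e7,
                             mode = c("calibrated", "constant")) {
  mode <- match.arg(mode)
  if (dna_pg_per_cell <= 0) stop("dna_pg_per_cell must be > 0",
                                 call. = FALSE)
  if (histones_per_cell <= 0) stop("histones_per_cell must be > 0",
                                   call. = FALSE)
  structure(list(dna_pg_per_cell = dna_pg_per_cell,
                 histones_per_cell = histones_per_cell,
                 mode = mode, calibration_factor = 1),
            class = "cell_count_model")
}

#' Histone amounts (fmol) per replicate
#'
#' amount = peptide light/heavy ratio x spiked heavy fmol, combined
#' over a histone's peptides by median.  A histone entirely
#' unquantified in a replicate is an error by default (the
#' normalization anchor is missing); with
#' `allow_missing_histones = TRUE` the remaining histones carry the
#' estimate.
#'
#' @param pratios peptide ratios from [peptide_ratios()]
#' @param spikes spike table from [read_spike_table()]
#' @param histone_genes identifiers of the four histone anchors
#' @param allow_missing_histones tolerate absent histones in a replicate
#' @return data.table: sample_id, replicate_id, histone, fmol
#' @export
histone_amounts <- function(pratios, spikes,
                            histone_genes = histone_gene_ids(),
                            allow_missing_histones = FALSE) {
  h <- as.data.table(pratios)[gene_id %in% histone_genes]
  if (!nrow(h))
    stop("no histone peptides found (looked for: ",
         paste(histone_genes, collapse = ", "), ")", call. = FALSE)
  h <- merge(h, as.data.table(spikes),
             by = c("gene_id", "peptide_seq", "sample_id"))
  h[, peptide_amount := ratio * heavy_amount]
  out <- h[, .(fmol = median(peptide_amount)),
           by = .(sample_id, replicate_id, histone = gene_id)]
  got <- out[, .N, by = .(sample_id, replicate_id)]
  short <- got[N < length(histone_genes)]
  if (nrow(short) && !allow_missing_histones)
    stop("histone anchor(s) missing in replicate(s): ",
         paste(short[, paste0(sample_id, "/", replicate_id)][1:min(5, .N)],
               collapse = ", "),
         "; use allow_missing_histones = TRUE to proceed on the median ",
         "of the remaining histones", call. = FALSE)
  setkey(out, sample_id, replicate_id, histone)
  out[]
}

#' Cells from total DNA mass
#'
#' `cells = total DNA mass (pg) / dna_pg_per_cell`.
#'
#' @param total_dna_mass_pg non-negative DNA mass in pg
#' @param model a [cell_count_model()]
#' @return cell count (real; fractional cells are meaningful for bulk)
#' @export
cells_from_dna <- function(total_dna_mass_pg, model = cell_count_model()) {
  if (any(total_dna_mass_pg < 0))
    stop("DNA mass must be >= 0", call. = FALSE)
  total_dna_mass_pg / model$dna_pg_per_cell
}

#' Inverse of [cells_from_dna()]
#' @param cells cell count
#' @param model a [cell_count_model()]
#' @return DNA mass in pg
#' @export
dna_from_cells <- function(cells, model = cell_count_model()) {
  cells * model$dna_pg_per_cell
}

#' Effective cell numbers from histone amounts
#'
#' Per replicate, the histone copy number is the median over the four
#' histones of `fmol x 1e-15 x N_A` (the median makes the ruler robust
#' to one aberrant histone).  In `constant` mode
#' `cells = copies / histones_per_cell`.  In `calibrated` mode the
#' factor `median over cell-line replicates of counted_cells / raw`
#' rescales all samples, removing any dependence on the
#' `histones_per_cell` constant.
#'
#' @param hist_amounts output of [histone_amounts()]
#' @param model a [cell_count_model()]
#' @param samples sample sheet (required in calibrated mode for
#'   `counted_cells`)
#' @return data.table: sample_id, replicate_id, effective_cells; the
#'   fitted model (with `calibration_factor`) in attribute `model`
#' @export
cells_from_histones <- function(hist_amounts, model = cell_count_model(),
                                samples = NULL) {
  ha <- as.data.table(hist_amounts)
  est <- ha[, .(copies = median(fmol * .MOL_PER_FMOL)),
            by = .(sample_id, replicate_id)]
  est[, raw_cells := copies / model$histones_per_cell]
  if (model$mode == "calibrated") {
    if (is.null(samples))
      stop("calibrated mode needs the sample sheet", call. = FALSE)
    sm <- as.data.table(samples)
    cal <- merge(est, sm[sample_class == "cell_line",
                         .(sample_id, counted_cells)], by = "sample_id")
    cal <- cal[is.finite(counted_cells) & counted_cells > 0]
    if (!nrow(cal))
      stop("calibrated mode needs >=1 cell-line sample with counted ",
           "cells; none found", call. = FALSE)
    model$calibration_factor <- cal[, median(counted_cells / raw_cells)]
  }
  est[, effective_cells := raw_cells * model$calibration_factor]
  bad <- est[!is.finite(effective_cells) | effective_cells <= 0]
  if (nrow(bad))
    stop("non-positive effective cell count in replicate(s): ",
         paste(bad[, paste0(sample_id, "/", replicate_id)][1:min(5, .N)],
               collapse = ", "), call. = FALSE)
  out <- est[, .(sample_id, replicate_id, effective_cells)]
  setattr(out, "model", model)
  setkey(out, sample_id, replicate_id)
  out[]
}

#' Normalization factors and tissue cell densities
#'
#' `norm_factor = 1 / effective_cells` is the divisor turning total
#' molecule counts in a replicate into copies per cell; for tissues,
#' `cells_per_mg = effective_cells / lysate_mass_mg` summarises cell
#' density per lysate mass.
#'
#' @param cell_counts output of [cells_from_histones()]
#' @param samples sample sheet
#' @return data.table: sample_id, replicate_id, effective_cells,
#'   norm_factor, cells_per_mg (NA for cell lines)
#' @export
normalization_factors <- function(cell_counts, samples) {
  cc <- as.data.table(cell_counts)
  sm <- as.data.table(samples)
  out <- merge(cc, sm[, .(sample_id, sample_class, lysate_mass_mg)],
               by = "sample_id")
  out[, norm_factor := 1 / effective_cells]
  out[, cells_per_mg := ifelse(sample_class == "tissue",
                               effective_cells / lysate_mass_mg, NA_real_)]
  out[, sample_class := NULL]
  out[, lysate_mass_mg := NULL]
  setattr(out, "model", attr(cell_counts, "model", exact = TRUE))
  setkey(out, sample_id, replicate_id)
  out[]
}
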