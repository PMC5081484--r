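## Absolute copies per cell.  The units audit lives in one place:
## copies/cell = (light/heavy ratio, dimensionless)
##             x (heavy spike, fmol) x (molecules per fmol)
##             / (effective cells in the replicate).

#' Peptide-level copies per cell
#'
#' Joins peptide ratios to spike amounts and per-replicate effective
#' cell counts and applies the unit conversion above.  A measured
#' peptide without a spike entry is an error naming the
#' (gene, peptide, sample).
#'
#' @param pratios peptide ratios from [peptide_ratios()]
#' @param spikes spike table
#' @param cell_counts per-replicate effective cells from
#'   [cells_from_histones()]
#' @return data.table: gene_id, peptide_seq, sample_id, replicate_id,
#'   copies (per cell)
#' @export
peptide_copies <- function(pratios, spikes, cell_counts) {
  pr <- as.data.table(pratios)
  sp <- as.data.table(spikes)
  cc <- as.data.table(cell_counts)
  m <- merge(pr, sp, by = c("gene_id", "peptide_seq", "sample_id"),
             all.x = TRUE)
  orphan <- m[is.na(heavy_amount)]
  if (nrow(orphan))
    stop(sprintf("no spike amount for (%s, %s, %s)",
                 orphan$gene_id[1], orphan$peptide_seq[1],
                 orphan$sample_id[1]), call. = FALSE)
  m <- merge(m, cc, by = c("sample_id", "replicate_id"))
  if (any(m$effective_cells <= 0))
    stop("effective cell counts must be > 0", call. = FALSE)
  m[, copies := ratio * heavy_amount * .MOL_PER_FMOL / effective_cells]
  m[, .(gene_id, peptide_seq, sample_id, replicate_id, copies)]
}

#' Roll peptide copies up to a gene x sample copy-number matrix
#'
#' Default order `peptides_first`: within each replicate, take the
#' median over peptides; then per gene-sample, the median over
#' replicates.  `replicates_first` medians each peptide over its
#' replicates first, then medians over peptides.  Both orders agree
#' when values are balanced; the one used is recorded in the `rollup`
#' attribute, and per-entry provenance (peptides/replicates used) in
#' attribute `provenance`.
#'
#' @param pepcopies output of [peptide_copies()]
#' @param rollup `"peptides_first"` or `"replicates_first"`
#' @return numeric matrix genes x samples (NA where a gene was not
#'   measured in a sample)
#' @export
protein_copies <- function(pepcopies,
                           rollup = c("peptides_first",
                                      "replicates_first")) {
  rollup <- match.arg(rollup)
  pc <- as.data.table(pepcopies)
  if (rollup == "peptides_first") {
    per_rep <- pc[, .(rep_value = median(copies), n_peptides = .N),
                  by = .(gene_id, sample_id, replicate_id)]
    cell <- per_rep[, .(copies_per_cell = median(rep_value),
                        n_peptides = max(n_peptides),
                        n_replicates = .N),
                    by = .(gene_id, sample_id)]
  } else {
    per_pep <- pc[, .(pep_value = median(copies), n_replicates = .N),
                  by = .(gene_id, sample_id, peptide_seq)]
    cell <- per_pep[, .(copies_per_cell = median(pep_value),
                        n_peptides = .N,
                        n_replicates = max(n_replicates)),
                    by = .(gene_id, sample_id)]
  }
  genes <- sort(unique(cell$gene_id))
  samples <- sort(unique(cell$sample_id))
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(cell$gene_id, cell$sample_id)] <- cell$copies_per_cell
  attr(m, "rollup") <- rollup
  attr(m, "provenance") <- cell
  m
}
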