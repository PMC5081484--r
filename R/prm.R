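## Light/heavy rollup: fragment ratios -> peptide ratios -> filters.

#' Per-fragment light/heavy ratios
#'
#' Computes `light area / heavy area` for every
#' (gene, peptide, fragment, sample, replicate) where both labels are
#' present and the heavy area is positive.  Fragments lacking either
#' label, or with a zero heavy area, yield no ratio and are tallied in
#' the `unusable` attribute rather than raising an error.
#'
#' @param records transition records from [read_transition_report()] or
#'   [generate_measurements()]
#' @return data.table with columns sample_id, replicate_id, gene_id,
#'   peptide_seq, fragment_ion, ratio; attribute `unusable` holds the
#'   skipped fragment keys
#' @export
fragment_ratios <- function(records) {
  wide <- dcast(as.data.table(records),
                sample_id + replicate_id + gene_id + peptide_seq +
                  fragment_ion ~ label, value.var = "area")
  if (!"light" %in% names(wide)) wide[, light := NA_real_]
  if (!"heavy" %in% names(wide)) wide[, heavy := NA_real_]
  usable <- !is.na(wide$light) & !is.na(wide$heavy) & wide$heavy > 0
  out <- wide[usable][, .(sample_id, replicate_id, gene_id, peptide_seq,
                          fragment_ion, ratio = light / heavy)]
  setattr(out, "unusable",
          wide[!usable, .(sample_id, replicate_id, gene_id, peptide_seq,
                          fragment_ion)])
  out[]
}

#' Roll fragment ratios up to peptide ratios
#'
#' Two combine policies are provided.  `median_of_fragments` (default)
#' takes the median of the per-fragment light/heavy ratios, robust to a
#' single interfered fragment.  `sum_areas` computes
#' `sum(light)/sum(heavy)` over usable fragments, the convention of
#' Skyline's native rollup; it weights fragments by intensity.  The
#' policy used is recorded in the `policy` attribute.
#'
#' @param records transition records
#' @param policy `"median_of_fragments"` or `"sum_areas"`
#' @param min_fragments minimum usable fragments for a peptide to be
#'   quantified in a replicate (default 1)
#' @return data.table with columns gene_id, peptide_seq, sample_id,
#'   replicate_id, ratio, n_fragments_used
#' @export
peptide_ratios <- function(records,
                           policy = c("median_of_fragments", "sum_areas"),
                           min_fragments = 1L) {
  policy <- match.arg(policy)
  records <- as.data.table(records)
  if (policy == "median_of_fragments") {
    fr <- fragment_ratios(records)
    out <- fr[, .(ratio = median(ratio), n_fragments_used = .N),
              by = .(gene_id, peptide_seq, sample_id, replicate_id)]
  } else {
    fr <- fragment_ratios(records)  # defines the usable fragment set
    usable <- fr[, .(gene_id, peptide_seq, sample_id, replicate_id,
                     fragment_ion)]
    wide <- dcast(records,
                  sample_id + replicate_id + gene_id + peptide_seq +
                    fragment_ion ~ label, value.var = "area")
    wide <- wide[usable, on = names(usable)]
    out <- wide[, .(ratio = sum(light) / sum(heavy),
                    n_fragments_used = .N),
                by = .(gene_id, peptide_seq, sample_id, replicate_id)]
  }
  out <- out[n_fragments_used >= min_fragments & is.finite(ratio) &
               ratio > 0]
  setattr(out, "policy", policy)
  setkey(out, gene_id, peptide_seq, sample_id, replicate_id)
  out[]
}

#' Quantifiability filter with exclusion report
#'
#' A gene is unquantified in a sample when it has no usable peptide
#' ratio in any replicate of that sample.  Under the default
#' `drop = "global"`, any such gene is removed from the entire analysis
#' (the whole-gene exclusion applied to assay panels whose endogenous
#' peptides fail in some sample); `drop = "per_sample"` removes only the
#' affected gene-sample pairs.
#'
#' @param pratios peptide ratios from [peptide_ratios()]
#' @param sample_ids full vector of expected sample ids (needed to
#'   detect samples where a gene is entirely absent)
#' @param drop `"global"` or `"per_sample"`
#' @param exempt_genes genes never dropped (the histone anchors by
#'   default; they are normalization infrastructure, not analytes)
#' @return list with `ratios` (filtered peptide ratios) and
#'   `exclusions` (data.table gene_id, reason, samples)
#' @export
filter_quantifiable <- function(pratios, sample_ids,
                                drop = c("global", "per_sample"),
                                exempt_genes = histone_gene_ids()) {
  drop <- match.arg(drop)
  pratios <- as.data.table(pratios)
  quant <- unique(pratios[, .(gene_id, sample_id)])
  genes <- setdiff(unique(pratios$gene_id), exempt_genes)
  full <- CJ(gene_id = genes, sample_id = sample_ids, sorted = FALSE)
  miss <- full[!quant, on = c("gene_id", "sample_id")]
  if (drop == "global") {
    excl <- miss[, .(reason = "unquantified in >=1 sample",
                     samples = paste(sort(sample_id), collapse = ";")),
                 by = gene_id]
    kept <- pratios[!gene_id %in% excl$gene_id]
  } else {
    excl <- miss[, .(reason = "unquantified in sample",
                     samples = sample_id), by = gene_id]
    kept <- pratios  # absent pairs are already absent rows
  }
  list(ratios = kept, exclusions = excl)
}
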