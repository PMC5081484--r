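## Readers/writers for the four tabular interfaces and result tables.
##
## Dialects: the transition report follows a Skyline-style English
## export by default; a named mapping lets other column headers be
## consumed without rewriting files.  Missing endogenous signal is an
## absent row, never a zero area; zeros are legal in TPM and handled
## downstream.  Identifiers are case-sensitive exact strings.

.TRANSITION_DIALECT <- c(
  sample_id = "Sample", replicate_id = "Replicate", gene_id = "Gene",
  peptide_seq = "Peptide", fragment_ion = "Fragment", label = "Label",
  area = "Area"
)

#' Read a transition-level quant report (CSV)
#'
#' Expects one integrated fragment-ion area per row with columns
#' Sample, Replicate, Gene, Peptide, Fragment, Label, Area (names
#' remappable via `dialect`).  Rejects duplicate
#' (sample, replicate, gene, peptide, fragment, label) keys and
#' negative or non-numeric areas, citing the offending row.
#'
#' @param path CSV file
#' @param dialect named character vector mapping the canonical field
#'   names to the file's column headers; defaults to the Skyline-style
#'   English export
#' @return a data.table of validated transition records
#' @export
read_transition_report <- function(path, dialect = .TRANSITION_DIALECT) {
  dialect <- unlist(utils::modifyList(as.list(.TRANSITION_DIALECT),
                                      as.list(dialect)))
  dt <- fread(path)
  miss <- setdiff(unname(dialect), names(dt))
  if (length(miss))
    stop("transition report is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  setnames(dt, unname(dialect), names(dialect))
  dt <- dt[, names(.TRANSITION_DIALECT), with = FALSE]
  for (col in c("sample_id", "replicate_id", "gene_id", "peptide_seq",
                "fragment_ion", "label"))
    set(dt, j = col, value = as.character(dt[[col]]))
  if (!nrow(dt)) {
    set(dt, j = "area", value = numeric())
    setkey(dt, sample_id, replicate_id, gene_id, peptide_seq,
           fragment_ion, label)
    return(dt[])
  }
  if (!is.numeric(dt$area)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt$area))))
    stop("non-numeric Area on row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(dt$area) | dt$area < 0)
  if (length(bad))
    stop("negative or missing Area on row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  if (!all(dt$label %in% c("light", "heavy")))
    stop("Label must be 'light' or 'heavy'", call. = FALSE)
  dup <- duplicated(dt, by = c("sample_id", "replicate_id", "gene_id",
                               "peptide_seq", "fragment_ion", "label"))
  if (any(dup)) {
    k <- dt[which(dup)[1]]
    stop(sprintf(
      "duplicate transition key: (%s, %s, %s, %s, %s, %s)",
      k$sample_id, k$replicate_id, k$gene_id, k$peptide_seq,
      k$fragment_ion, k$label), call. = FALSE)
  }
  setkey(dt, sample_id, replicate_id, gene_id, peptide_seq,
         fragment_ion, label)
  dt[]
}

#' @rdname read_transition_report
#' @param records data.table of transition records
#' @export
write_transition_report <- function(records, path) {
  out <- records[, .(Sample = sample_id, Replicate = replicate_id,
                     Gene = gene_id, Peptide = peptide_seq,
                     Fragment = fragment_ion, Label = label, Area = area)]
  fwrite(out, path)
  invisible(path)
}

#' Read/write the heavy spike-in table (TSV)
#'
#' One row per (gene, peptide, sample) with the spiked heavy-standard
#' amount in fmol; amounts must be strictly positive and keys unique.
#'
#' @param path TSV file with columns Gene, Peptide, Sample,
#'   HeavyAmount_fmol
#' @return a keyed data.table
#' @export
read_spike_table <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("Gene", "Peptide", "Sample", "HeavyAmount_fmol")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("spike table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  setnames(dt, need, c("gene_id", "peptide_seq", "sample_id",
                       "heavy_amount"))
  for (col in c("gene_id", "peptide_seq", "sample_id"))
    set(dt, j = col, value = as.character(dt[[col]]))
  if (any(!is.finite(dt$heavy_amount) | dt$heavy_amount <= 0))
    stop("spike amounts must be finite and > 0", call. = FALSE)
  if (anyDuplicated(dt, by = c("gene_id", "peptide_seq", "sample_id")))
    stop("duplicate (gene, peptide, sample) in spike table", call. = FALSE)
  setkey(dt, gene_id, peptide_seq, sample_id)
  dt[]
}

#' @rdname read_spike_table
#' @param spikes data.table as returned by [read_spike_table()]
#' @export
write_spike_table <- function(spikes, path) {
  out <- spikes[, .(Gene = gene_id, Peptide = peptide_seq,
                    Sample = sample_id, HeavyAmount_fmol = heavy_amount)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read/write the sample sheet (TSV)
#'
#' Columns Sample, Class (`cell_line`/`tissue`), Replicates
#' (semicolon-separated ids), CountedCells (cell lines), LysateMass_mg
#' (tissues).  Cell lines must carry counted cells; tissues must carry
#' a lysate mass.
#'
#' @param path TSV file
#' @return a data.table with a list-column `replicate_ids`
#' @export
read_sample_sheet <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("Sample", "Class", "Replicates", "CountedCells",
            "LysateMass_mg")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("sample sheet is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  setnames(dt, need, c("sample_id", "sample_class", "replicates",
                       "counted_cells", "lysate_mass_mg"))
  for (col in c("sample_id", "sample_class", "replicates"))
    set(dt, j = col, value = as.character(dt[[col]]))
  if (!all(dt$sample_class %in% c("cell_line", "tissue")))
    stop("sample Class must be 'cell_line' or 'tissue'", call. = FALSE)
  if (anyDuplicated(dt$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  dt[, counted_cells := as.numeric(counted_cells)]
  dt[, lysate_mass_mg := as.numeric(lysate_mass_mg)]
  bad <- dt[sample_class == "cell_line" &
              (!is.finite(counted_cells) | counted_cells <= 0), sample_id]
  if (length(bad))
    stop("cell_line sample(s) without CountedCells: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- dt[sample_class == "tissue" &
              (!is.finite(lysate_mass_mg) | lysate_mass_mg <= 0), sample_id]
  if (length(bad))
    stop("tissue sample(s) without LysateMass_mg: ",
         paste(bad, collapse = ", "), call. = FALSE)
  dt[, replicate_ids := strsplit(replicates, ";", fixed = TRUE)]
  dt[, replicates := NULL]
  setcolorder(dt, c("sample_id", "sample_class", "replicate_ids",
                    "counted_cells", "lysate_mass_mg"))
  dt[]
}

#' @rdname read_sample_sheet
#' @param samples data.table as returned by [read_sample_sheet()]
#' @export
write_sample_sheet <- function(samples, path) {
  out <- data.table(
    Sample = samples$sample_id,
    Class = samples$sample_class,
    Replicates = vapply(samples$replicate_ids, paste, "", collapse = ";"),
    CountedCells = samples$counted_cells,
    LysateMass_mg = samples$lysate_mass_mg
  )
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read/write a TPM matrix (TSV, genes as rows)
#'
#' First column `Gene`, one column per sample; entries are
#' transcripts-per-million and must be non-negative.
#'
#' @param path TSV file
#' @return a numeric matrix, genes x samples
#' @export
read_tpm_matrix <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "Gene"))
  if (names(dt)[1] != "Gene")
    stop("TPM matrix must have 'Gene' as its first column", call. = FALSE)
  if (anyDuplicated(dt$Gene))
    stop("duplicate gene ids in TPM matrix", call. = FALSE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$Gene
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0))
    stop("TPM values must be finite and >= 0", call. = FALSE)
  m
}

#' @rdname read_tpm_matrix
#' @param tpm numeric matrix, genes x samples
#' @export
write_tpm_matrix <- function(tpm, path) {
  if (!ncol(tpm)) {
    writeLines("Gene", path)
    return(invisible(path))
  }
  dt <- data.table(Gene = rownames(tpm))
  dt <- cbind(dt, as.data.table(tpm))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Cross-validate a measurement bundle
#'
#' Checks that sample sets agree across the four tables, that every
#' (gene, peptide, sample) appearing in the transitions has a spike
#' amount, and that replicate ids in the transitions are declared in
#' the sample sheet.
#'
#' @param bundle an `rtp_bundle` (or a list with elements
#'   `transitions`, `spikes`, `samples`, `tpm`)
#' @return the bundle, invisibly; errors list the asymmetric difference
#' @export
validate_bundle <- function(bundle) {
  tr <- bundle$transitions; sp <- bundle$spikes
  sm <- bundle$samples; tpm <- bundle$tpm
  sheet_samples <- sm$sample_id
  sym <- function(a, b) union(setdiff(a, b), setdiff(b, a))
  d <- sym(colnames(tpm), sheet_samples)
  if (length(d))
    stop("sample sets differ between TPM matrix and sample sheet: ",
         paste(d, collapse = ", "), call. = FALSE)
  d <- setdiff(unique(tr$sample_id), sheet_samples)
  if (length(d))
    stop("transition samples absent from sample sheet: ",
         paste(d, collapse = ", "), call. = FALSE)
  need <- unique(tr[, .(gene_id, peptide_seq, sample_id)])
  have <- sp[, .(gene_id, peptide_seq, sample_id)]
  orphan <- need[!have, on = c("gene_id", "peptide_seq", "sample_id")]
  if (nrow(orphan))
    stop(sprintf(
      "no spike amount for measured (gene, peptide, sample): (%s, %s, %s)%s",
      orphan$gene_id[1], orphan$peptide_seq[1], orphan$sample_id[1],
      if (nrow(orphan) > 1) sprintf(" and %d more", nrow(orphan) - 1) else ""),
      call. = FALSE)
  declared <- sm[, .(replicate_id = unlist(replicate_ids)), by = sample_id]
  used <- unique(tr[, .(sample_id, replicate_id)])
  orphan <- used[!declared, on = c("sample_id", "replicate_id")]
  if (nrow(orphan))
    stop("transition replicate(s) not declared in sample sheet: ",
         paste(orphan[, paste0(sample_id, "/", replicate_id)][1:min(5, .N)],
               collapse = ", "), call. = FALSE)
  invisible(bundle)
}

#' Write a result table with a provenance comment header
#'
#' Emits a `# rtpquant <version> ...` comment line followed by a TSV
#' body; [read_result_table()] skips the comment.
#'
#' @param dt data.frame/data.table to write
#' @param path output path
#' @param meta named character vector folded into the comment line
#' @export
write_result_table <- function(dt, path, meta = character()) {
  hdr <- sprintf("# rtpquant %s%s",
                 as.character(utils::packageVersion("rtpquant")),
                 if (length(meta))
                   paste0("; ", paste(names(meta), meta, sep = "=",
                                      collapse = "; "))
                 else "")
  writeLines(hdr, path)
  fwrite(as.data.table(dt), path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  fread(path, sep = "\t", skip = 1L)
}
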