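## Gene-specific RNA-to-protein (RTP) conversion factors, leave-one-out
## prediction, and the correlation summaries.
##
## Conventions: Pearson correlations between abundance-scale quantities
## are computed on log10 values over pairwise-complete strictly
## positive pairs (log axes are the natural scale for quantities
## spanning orders of magnitude); Spearman uses average ranks of the
## raw values over the same pairs.

log10_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3L) return(NA_real_)
  cor(log10(x[ok]), log10(y[ok]))
}

raw_spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3L) return(NA_real_)
  cor(x[ok], y[ok], method = "spearman")
}

align_matrices <- function(copies, tpm) {
  genes <- intersect(rownames(copies), rownames(tpm))
  samples <- intersect(colnames(copies), colnames(tpm))
  if (!length(genes))
    stop("copy-number and TPM matrices share no genes", call. = FALSE)
  if (!length(samples))
    stop("copy-number and TPM matrices share no samples", call. = FALSE)
  list(copies = copies[genes, samples, drop = FALSE],
       tpm = tpm[genes, samples, drop = FALSE])
}

#' Per-gene, per-sample RTP ratios
#'
#' `RTP[g, s] = copies[g, s] / TPM[g, s]` on the aligned gene/sample
#' intersection.  Pairs with TPM = 0 or absent copies yield NA and are
#' tallied in attribute `dropped` (counts by reason).
#'
#' @param copies gene x sample copy-number matrix
#' @param tpm gene x sample TPM matrix
#' @return gene x sample matrix of RTP factors (copies per TPM unit)
#' @export
rtp_ratios <- function(copies, tpm) {
  al <- align_matrices(copies, tpm)
  rtp <- al$copies / al$tpm
  rtp[al$tpm == 0] <- NA_real_
  attr(rtp, "dropped") <- c(
    tpm_zero = sum(al$tpm == 0 & !is.na(al$copies)),
    copies_absent = sum(is.na(al$copies))
  )
  rtp
}

#' Gene-level RTP summary
#'
#' The gene-specific conversion factor is the median of its per-sample
#' RTP values (`center = "mean"` is available for comparison); the
#' spread is the coefficient of variation (sd/mean) of the linear
#' per-sample RTP values.
#'
#' @param rtp gene x sample RTP matrix from [rtp_ratios()]
#' @param min_samples minimum defined per-sample values for a gene to
#'   get a conversion factor (default 2); genes below it are flagged
#'   in attribute `flagged` and excluded
#' @param center `"median"` (default) or `"mean"`
#' @return data.table: gene_id, rtp_central, rtp_cv, n_samples_used
#' @export
gene_rtp <- function(rtp, min_samples = 2L, center = c("median", "mean")) {
  center <- match.arg(center)
  cfun <- if (center == "median") median else mean
  n_used <- rowSums(!is.na(rtp))
  keep <- n_used >= min_samples
  out <- data.table(
    gene_id = rownames(rtp)[keep],
    rtp_central = apply(rtp[keep, , drop = FALSE], 1, cfun, na.rm = TRUE),
    rtp_cv = apply(rtp[keep, , drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]
      sd(v) / mean(v)
    }),
    n_samples_used = n_used[keep]
  )
  setattr(out, "flagged", rownames(rtp)[!keep])
  setattr(out, "center", center)
  out[]
}

#' Per-gene RNA-protein correlations across samples
#'
#' For each gene with at least 3 paired positive values: Pearson's r on
#' log10 copies vs log10 TPM, Spearman's rho on the raw values, and
#' r squared.
#'
#' @inheritParams rtp_ratios
#' @return data.table: gene_id, pearson_loglog, spearman, r_squared,
#'   n_pairs
#' @export
gene_correlations <- function(copies, tpm) {
  al <- align_matrices(copies, tpm)
  rbindlist(lapply(rownames(al$copies), function(g) {
    x <- al$copies[g, ]; y <- al$tpm[g, ]
    ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
    r <- log10_pearson(x, y)
    data.table(gene_id = g, pearson_loglog = r,
               spearman = raw_spearman(x, y),
               r_squared = r^2, n_pairs = sum(ok))
  }))
}

#' Leave-one-out RNA-based prediction of protein copy numbers
#'
#' For each sample s, the gene-specific conversion factor is the median
#' of that gene's RTP values over all other samples; the prediction is
#' `TPM[g, s] x RTP_loo[g]`.  Per-sample performance is the Pearson
#' (log10) and Spearman of predicted vs measured copies across genes;
#' the direct TPM-vs-copies correlation (no conversion factor) is
#' reported alongside as the baseline.
#'
#' @inheritParams rtp_ratios
#' @param center `"median"` (default) or `"mean"` out-of-sample summary
#' @return list: `predicted` (gene x sample matrix),
#'   `sample_correlations` (data.table: sample_id, pearson_loglog,
#'   spearman, direct_pearson_loglog, direct_spearman, n_genes),
#'   `summary` (named medians across samples), `omitted` (genes with no
#'   out-of-sample RTP, per sample)
#' @export
predict_loo <- function(copies, tpm, center = c("median", "mean")) {
  center <- match.arg(center)
  cfun <- if (center == "median") median else mean
  al <- align_matrices(copies, tpm)
  if (ncol(al$copies) < 2L)
    stop("leave-one-out prediction needs >= 2 samples", call. = FALSE)
  rtp <- rtp_ratios(al$copies, al$tpm)
  samples <- colnames(al$copies)
  pred <- matrix(NA_real_, nrow(al$copies), length(samples),
                 dimnames = dimnames(al$copies))
  omitted <- list()
  for (s in samples) {
    loo <- apply(rtp[, samples != s, drop = FALSE], 1, cfun, na.rm = TRUE)
    loo[!is.finite(loo)] <- NA_real_
    omitted[[s]] <- rownames(rtp)[is.na(loo)]
    pred[, s] <- al$tpm[, s] * loo
  }
  sc <- rbindlist(lapply(samples, function(s) {
    p <- pred[, s]; m <- al$copies[, s]; t <- al$tpm[, s]
    ok <- is.finite(p) & is.finite(m) & p > 0 & m > 0
    data.table(sample_id = s,
               pearson_loglog = log10_pearson(p, m),
               spearman = raw_spearman(p, m),
               direct_pearson_loglog = log10_pearson(t, m),
               direct_spearman = raw_spearman(t, m),
               n_genes = sum(ok))
  }))
  list(predicted = pred,
       sample_correlations = sc,
       summary = c(
         median_pearson = median(sc$pearson_loglog, na.rm = TRUE),
         median_spearman = median(sc$spearman, na.rm = TRUE),
         median_direct_pearson = median(sc$direct_pearson_loglog,
                                        na.rm = TRUE)),
       omitted = omitted)
}

#' Pearson test with Fisher-Z confidence interval (closed form)
#'
#' Computes r, the t statistic `r sqrt((n-2)/(1-r^2))` with its
#' two-sided p from the t distribution on n-2 df, and the asymptotic
#' confidence interval from Fisher's Z transform
#' `atanh(r) +/- z_(1-a/2) / sqrt(n-3)`.  Written out explicitly so it
#' can be checked against `stats::cor.test`.
#'
#' @param x,y numeric vectors
#' @param conf_level confidence level (default 0.95)
#' @return list: r, t, df, p_value, conf_int, n
#' @export
pearson_test <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("pearson_test needs >= 4 complete pairs", call. = FALSE)
  r <- cor(x, y)
  df <- n - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  list(r = r, t = t_stat, df = df, p_value = p, conf_int = ci, n = n)
}

#' RTP spread and level versus protein length
#'
#' Correlates per-gene RTP coefficient of variation and (log10) central
#' RTP against protein length, with the Pearson t test and Fisher-Z
#' interval of [pearson_test()].
#'
#' @param rtp_table output of [gene_rtp()]
#' @param lengths data.frame with columns gene_id, length (amino acids)
#' @return list with elements `cv_vs_length` and `rtp_vs_length`, each
#'   a [pearson_test()] result, plus `n_genes`
#' @export
rtp_length_analysis <- function(rtp_table, lengths) {
  m <- merge(as.data.table(rtp_table),
             as.data.table(lengths)[, .(gene_id, length)], by = "gene_id")
  if (nrow(m) < 4L)
    stop("length analysis needs >= 4 genes with lengths", call. = FALSE)
  list(cv_vs_length = pearson_test(m$rtp_cv, m$length),
       rtp_vs_length = pearson_test(log10(m$rtp_central), m$length),
       n_genes = nrow(m))
}

#' Pooled two-sample Student t test (closed form)
#'
#' Equal-variance two-sided t test, written out so it can be checked
#' against `stats::t.test(var.equal = TRUE)`.
#'
#' @param a,b numeric vectors (each length >= 2)
#' @return list: t, df, p_value, mean_a, mean_b
#' @export
pooled_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("pooled_t_test needs >= 2 values per group", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  list(t = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' RTP comparison across subcellular compartments
#'
#' For each compartment with at least 2 annotated genes: pooled t test
#' of log10 central RTP, members versus all non-members.
#'
#' @param rtp_table output of [gene_rtp()]
#' @param compartments data.frame with columns gene_id, compartment
#'   (a gene may appear under several compartments)
#' @return data.table: compartment, n_in, n_out, mean_in, mean_out
#'   (log10 RTP), t, p_value; compartments skipped for size are listed
#'   in attribute `skipped`
#' @export
compartment_comparison <- function(rtp_table, compartments) {
  rt <- as.data.table(rtp_table)
  ann <- as.data.table(compartments)
  vals <- stats::setNames(log10(rt$rtp_central), rt$gene_id)
  comps <- unique(ann$compartment)
  skipped <- character()
  rows <- list()
  for (cp in comps) {
    members <- intersect(ann[compartment == cp, gene_id], names(vals))
    inside <- vals[members]
    outside <- vals[setdiff(names(vals), members)]
    if (length(inside) < 2L || length(outside) < 2L) {
      skipped <- c(skipped, cp)
      next
    }
    tt <- pooled_t_test(inside, outside)
    rows[[cp]] <- data.table(compartment = cp,
                             n_in = length(inside),
                             n_out = length(outside),
                             mean_in = tt$mean_a, mean_out = tt$mean_b,
                             t = tt$t, p_value = tt$p_value)
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(compartment = character(), n_in = integer(),
               n_out = integer(), mean_in = numeric(),
               mean_out = numeric(), t = numeric(), p_value = numeric())
  setattr(out, "skipped", skipped)
  out[]
}
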