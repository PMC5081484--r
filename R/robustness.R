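## Training-set-size robustness: how many samples are needed to pin
## down a usable conversion factor?  Random training subsets of size k
## define the per-gene RTP (median over the subset); every held-out
## sample is predicted and its log-log Pearson across genes recorded,
## until the requested number of predictions per size accumulates.

#' Cross-validation curve over training-set sizes
#'
#' For each size k in `sizes`, training subsets of k samples are drawn
#' uniformly without replacement (independently per iteration; repeats
#' across iterations possible).  The per-gene conversion factor is the
#' median RTP over the training samples; each of the n - k held-out
#' samples contributes one prediction event (its Pearson r of log10
#' predicted vs measured copies across genes).  Drawing stops once
#' `n_predictions_per_size` events are recorded (`count =
#' "predictions"`, default) or after that many subsets
#' (`count = "subsets"`).
#'
#' @param copies gene x sample copy-number matrix
#' @param tpm gene x sample TPM matrix
#' @param sizes training-set sizes, each in `[1, n_samples - 1]`
#' @param n_predictions_per_size events per size (default 5000)
#' @param seed integer seed; the curve is a pure function of
#'   (data, sizes, seed)
#' @param count what `n_predictions_per_size` counts
#' @return a `cv_result` list: `per_size` (named list of numeric
#'   vectors of Pearson values), `sizes`, `seed`, `n_iterations`
#' @export
cv_curve <- function(copies, tpm, sizes = NULL,
                     n_predictions_per_size = 5000L, seed = 1L,
                     count = c("predictions", "subsets")) {
  count <- match.arg(count)
  al <- align_matrices(copies, tpm)
  n <- ncol(al$copies)
  if (n < 2L) stop("cross-validation needs >= 2 samples", call. = FALSE)
  if (is.null(sizes)) sizes <- seq_len(n - 1L)
  if (any(sizes < 1L | sizes >= n))
    stop("training sizes must lie in [1, n_samples - 1]", call. = FALSE)
  rtp <- rtp_ratios(al$copies, al$tpm)
  logc <- log10(al$copies)
  logt <- log10(al$tpm)
  set.seed(sub_seed(seed, "cv"))
  per_size <- vector("list", length(sizes))
  names(per_size) <- as.character(sizes)
  iters <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    vals <- numeric(0)
    it <- 0L
    repeat {
      it <- it + 1L
      train <- sample.int(n, k)
      loo <- apply(rtp[, train, drop = FALSE], 1, median, na.rm = TRUE)
      loo[!is.finite(loo)] <- NA_real_
      llo <- log10(loo)
      for (s in setdiff(seq_len(n), train)) {
        p <- llo + logt[, s]
        m <- logc[, s]
        ok <- is.finite(p) & is.finite(m)
        r <- if (sum(ok) >= 3L) cor(p[ok], m[ok]) else NA_real_
        vals <- c(vals, r)
      }
      done <- if (count == "predictions")
        length(vals) >= n_predictions_per_size
      else it >= n_predictions_per_size
      if (done) break
    }
    per_size[[i]] <- if (count == "predictions")
      vals[seq_len(n_predictions_per_size)] else vals
    iters[i] <- it
  }
  structure(list(per_size = per_size, sizes = sizes, seed = seed,
                 n_iterations = iters, count = count),
            class = "cv_result")
}

#' Box-plot summary of a cross-validation curve
#'
#' Per training size: median, first/third quartiles (type-7,
#' linear-interpolation quantiles), whisker bounds at 1.5 x IQR
#' (clipped to the observed range), outliers beyond the whiskers, and
#' the number of prediction events.
#'
#' @param result a `cv_result` from [cv_curve()]
#' @return data.table: size, median, q1, q3, whisker_low, whisker_high,
#'   n_predictions, n_outliers; outlier values in attribute `outliers`
#' @export
summarize_cv <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  outliers <- list()
  out <- rbindlist(lapply(seq_along(result$sizes), function(i) {
    v <- result$per_size[[i]]
    v <- v[is.finite(v)]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    outl <- v[v < lo | v > hi]
    outliers[[as.character(result$sizes[i])]] <<- outl
    data.table(size = result$sizes[i], median = q[2], q1 = q[1],
               q3 = q[3],
               whisker_low = min(v[v >= lo]),
               whisker_high = max(v[v <= hi]),
               n_predictions = length(v), n_outliers = length(outl))
  }))
  setattr(out, "outliers", outliers)
  out[]
}
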