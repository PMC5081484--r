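mk_mat <- function(v, genes, samples) {
  matrix(v, length(genes), length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

test_that("rtp_ratios is element-wise division with zero-TPM tallying", {
  copies <- mk_mat(c(4000, 1000, 4000, 9000), "G1", paste0("S", 1:4))
  tpm <- mk_mat(c(20, 10, 20, 30), "G1", paste0("S", 1:4))
  r <- rtp_ratios(copies, tpm)
  expect_equal(as.vector(r), c(200, 100, 200, 300))

  tpm[1, 2] <- 0
  copies[1, 3] <- NA
  r <- rtp_ratios(copies, tpm)
  expect_true(is.na(r[1, 2]) && is.na(r[1, 3]))
  expect_identical(attr(r, "dropped"),
                   c(tpm_zero = 1L, copies_absent = 1L))
  expect_error(rtp_ratios(mk_mat(1, "X1", "S1"), mk_mat(1, "Y1", "S1")),
               "genes")
})

test_that("gene_rtp central values and cv match hand arithmetic", {
  rtp <- rbind(
    A = c(100, 200, 300),
    B = c(70, 70, 70),
    C = c(100, 100, 400),
    D = c(5, NA, NA))                     # below min_samples
  colnames(rtp) <- paste0("S", 1:3)
  tab <- gene_rtp(rtp, min_samples = 2L)
  expect_equal(tab[gene_id == "A", rtp_central], oracle_median(c(100, 200, 300)))
  expect_equal(tab[gene_id == "B", rtp_cv], 0)
  expect_equal(tab[gene_id == "C", rtp_central], 100)
  expect_equal(tab[gene_id == "C", rtp_cv], sd(c(100, 100, 400)) / 200)
  expect_false("D" %in% tab$gene_id)
  expect_identical(attr(tab, "flagged"), "D")
  ## mean alternative
  expect_equal(gene_rtp(rtp, center = "mean")[gene_id == "A", rtp_central],
               200)
})

test_that("gene correlations behave on proportional, log-linear and anti-ordered data", {
  tpm <- mk_mat(c(1, 10, 100, 1000, 17), "G1", paste0("S", 1:5))
  ## copies = c * TPM -> r = rho = 1
  g <- gene_correlations(tpm * 55, tpm)
  expect_equal(g$pearson_loglog, 1)
  expect_equal(g$spearman, 1)
  ## copies = TPM^2: log-log exact, linear Pearson below 1
  g <- gene_correlations(tpm ^ 2, tpm)
  expect_equal(g$pearson_loglog, 1)
  expect_lt(cor(as.vector(tpm ^ 2), as.vector(tpm)), 1)
  expect_equal(g$r_squared, 1)
  ## anti-ordered (copies a decreasing transform of TPM) -> rho = -1
  anti <- mk_mat(1 / as.vector(tpm), "G1", paste0("S", 1:5))
  expect_equal(gene_correlations(anti, tpm)$spearman, -1)
  ## fewer than 3 positive pairs -> absent
  few <- mk_mat(c(10, 20, 0, 0, 0), "G1", paste0("S", 1:5))
  expect_true(is.na(gene_correlations(few, tpm)$pearson_loglog))
})

test_that("leave-one-out predictions exclude the held-out sample", {
  ## per-sample RTP [100, 200, 300]: predicting S2 uses median(100, 300)
  tpm <- mk_mat(c(10, 10, 10), "G1", paste0("S", 1:3))
  copies <- mk_mat(c(1000, 2000, 3000), "G1", paste0("S", 1:3))
  loo <- predict_loo(copies, tpm)
  expect_equal(loo$predicted[["G1", "S2"]], 10 * oracle_median(c(100, 300)))
  expect_equal(loo$predicted[["G1", "S1"]], 10 * oracle_median(c(200, 300)))
  expect_error(predict_loo(copies[, 1, drop = FALSE],
                           tpm[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("LOO hygiene: perturbing a sample never changes its own prediction", {
  bb <- make_bundle(tiny_config())
  cp <- pipeline_copies(bb$bundle)
  tpm <- bb$bundle$tpm
  ref <- predict_loo(cp, tpm)
  for (s in c("CL01", "TS03")) {
    tampered <- cp
    tampered[, s] <- tampered[, s] * 1e3
    out <- predict_loo(tampered, tpm)
    expect_equal(out$predicted[, s], ref$predicted[, s])
  }
})

test_that("TPM rescaling divides RTP and leaves correlation structure alone", {
  bb <- make_bundle(tiny_config())
  cp <- pipeline_copies(bb$bundle)
  tpm <- bb$bundle$tpm
  for (c_scale in c(0.1, 3)) {
    r1 <- rtp_ratios(cp, tpm)
    r2 <- rtp_ratios(cp, tpm * c_scale)
    expect_equal(r2, r1 / c_scale, tolerance = 1e-12, ignore_attr = TRUE)
    l1 <- predict_loo(cp, tpm)
    l2 <- predict_loo(cp, tpm * c_scale)
    expect_equal(l2$sample_correlations, l1$sample_correlations,
                 tolerance = 1e-12)
    g1 <- gene_correlations(cp, tpm)
    g2 <- gene_correlations(cp, tpm * c_scale)
    expect_equal(g2$pearson_loglog, g1$pearson_loglog, tolerance = 1e-12)
  }
})

test_that("pearson_test reproduces cor.test (t statistic, p, Fisher-Z CI)", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    ours <- pearson_test(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate))
    expect_equal(ours$t, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
    expect_equal(ours$conf_int, as.vector(ref$conf.int), tolerance = 1e-10)
  }
  ## perfect correlation: t diverges, p -> 0, Fisher-Z CI pinned at 1
  perf <- pearson_test(1:10, 2 * (1:10) + 5)
  expect_equal(perf$r, 1)
  expect_equal(perf$p_value, 0)
  expect_equal(perf$conf_int, c(1, 1))
})

test_that("rtp_length_analysis wires the Pearson test to the RTP table", {
  rtab <- data.table(gene_id = paste0("G", 1:10),
                     rtp_central = 10 ^ seq(2, 4.5, length.out = 10),
                     rtp_cv = seq(0.1, 0.9, length.out = 10),
                     n_samples_used = 10L)
  lens <- data.table(gene_id = paste0("G", 1:10),
                     length = c(120, 340, 90, 515, 222, 410, 150, 610,
                                275, 385))
  la <- rtp_length_analysis(rtab, lens)
  ref <- cor.test(rtab$rtp_cv, lens$length)
  expect_equal(la$cv_vs_length$r, unname(ref$estimate))
  expect_equal(la$cv_vs_length$p_value, ref$p.value)
  ref2 <- cor.test(log10(rtab$rtp_central), lens$length)
  expect_equal(la$rtp_vs_length$conf_int, as.vector(ref2$conf.int),
               tolerance = 1e-10)
  expect_error(rtp_length_analysis(rtab[1:3], lens), ">= 4")
})

test_that("pooled_t_test and compartment_comparison match t.test(var.equal)", {
  ## hand-computed 3-vs-3: a = (1,2,3), b = (2,4,6)
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  ours <- pooled_t_test(a, b)
  expect_equal(ours$t, t_manual)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)

  ## identical groups -> t = 0, p = 1
  same <- pooled_t_test(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  ## compartment wiring: a +1 log10 shift separates cleanly
  set.seed(9)
  rtab <- data.table(gene_id = paste0("G", 1:20),
                     rtp_central = 10 ^ c(rnorm(10, 3, 0.05),
                                          rnorm(10, 4, 0.05)),
                     rtp_cv = 0.2, n_samples_used = 20L)
  ann <- data.table(gene_id = paste0("G", 11:20),
                    compartment = "extracellular")
  cmp <- compartment_comparison(rtab, ann)
  expect_lt(cmp$p_value, 1e-6)
  expect_gt(cmp$mean_in, cmp$mean_out)
  ref <- t.test(log10(rtab$rtp_central[11:20]),
                log10(rtab$rtp_central[1:10]), var.equal = TRUE)
  expect_equal(cmp$t, unname(ref$statistic))
  ## undersized group skipped and reported
  tiny <- compartment_comparison(rtab,
                                 data.table(gene_id = "G1",
                                            compartment = "lonely"))
  expect_identical(nrow(tiny), 0L)
  expect_identical(attr(tiny, "skipped"), "lonely")
})
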