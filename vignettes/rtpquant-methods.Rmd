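---
title: "rtpquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rtpquant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtpquant)
```

## The quantification model

`rtpquant` operates on the standard currency of spike-in targeted
proteomics: the ratio between an endogenous ("light") peptide and a
co-digested stable-isotope-labelled ("heavy") standard of known
amount. Because the standard traverses digestion and clean-up together
with the sample, the ratio is immune to losses that occur after
spiking; the absolute amount of endogenous peptide in the processed
aliquot is simply `ratio × spiked fmol`.

Converting amounts to copies per cell requires the number of cells in
the aliquot, which cannot be counted for tissue lysates. The package
uses the histone ruler: the four core histones are laid down on DNA at
one nucleosome per ~200 bp with two copies of each core histone per
nucleosome, so their molar amount is proportional to DNA content and
therefore to the number of (2N-equivalent) cells:

> cells = histone copies / histones-per-cell, with histones-per-cell ≈
> 6.4e9 bp / 200 bp × 2 ≈ 6.4e7.

Two modes are provided. `constant` divides by that constant directly.
`calibrated` (the default whenever counted cell-line aliquots exist)
fits one multiplicative factor so the histone-derived estimates match
the counted cells, and applies it to all samples — this removes the
dependence on the constant, and with it any worry about its exact
value or about ploidy differences between a diploid reference and the
real karyotype. Aneuploid cell lines are otherwise *not* corrected
for: the ruler is honest about being a 2N-equivalent count. The DNA
proxy `cells ≈ mass / 3.59 pg` is exposed (`cells_from_dna()`) with
the constant configurable, noting that 3.59 pg is lower than the
commonly cited ~6.5 pg diploid value; we keep the value as adopted in
the histone-ruler literature and let `calibrated` mode make it moot.

The median is used at every combine step — fragments to peptides,
peptides to histone amounts, the four histones to one copy estimate,
peptide copies to protein copies, per-sample RTP values to the gene
factor. Intensity-scale data carry occasional gross outliers
(interference on one fragment, a modified peptide) and the median is
the simplest estimator robust to one bad member; the conserved
inter-histone ratios observed in practice justify treating each
histone as a control for the others. Where the combine rule is
genuinely ambiguous we expose both readings: `sum_areas` as the
fragment-level alternative (Skyline's native rollup, intensity
weighted), and `replicates_first` as the alternative rollup order; the
choice is recorded in output metadata so results are self-describing.

## RTP factors and prediction

For gene *g* and sample *s*, `RTP[g, s] = copies[g, s] / TPM[g, s]`
(protein copies per cell per TPM unit). The gene-specific conversion
factor is the **median** across samples (`center = "mean"` exists for
comparison only). Predictions multiply a sample's TPM by a factor
estimated *excluding that sample* (leave-one-out), so reported
correlations measure transferability, not overfitting.

Correlation conventions: Pearson correlations between abundance-scale
quantities are computed on log10 values over pairwise-complete,
strictly positive pairs — abundances span orders of magnitude and are
compared on log axes; Spearman uses average ranks of the raw values
(rank-invariant, ties averaged). Pairs with TPM = 0 or absent copies
are excluded pairwise and tallied; zero and "not measured" are kept
distinct throughout (a missing measurement is an absent row, never a
zero area).

The training-set-size analysis (`cv_curve()`) draws training subsets
of size k uniformly without replacement, independently per iteration,
and records one Pearson value per held-out sample until a fixed number
of prediction events accumulates (default 5,000 per size; the
alternative reading — counting subsets — is `count = "subsets"`).
Box summaries use type-7 (linear interpolation) quartiles and
1.5 × IQR whiskers.

## The synthetic world

`sim_config()` defaults describe the stated study design, not a
convenient test dial: 55 genes across 9 cell lines and 11 tissues in
triplicate; peptide coverage 24/13/11/5/2 genes with 1–5 peptides;
3–6 fragment ions per peptide; four histone anchors in every
replicate; gene-specific true RTP factors log-uniform over
[200, 220,000] (the printed extreme range, spread over ~3 orders of
magnitude with no stated distribution — log-uniform is the
least-informative choice on that scale); multiplicative log-normal
noise at the copy level (sd 0.12 log10; biology + preparation) and the
fragment level (sd 0.05 log10; instrument, with replicate-to-replicate
variability folded in since no separate replicate model is stated);
2% of gene–sample pairs blanked whole (the observed failure mode is a
gene unquantifiable in a sample, not single fragments); cell-line
aliquots of exactly 1e6 counted cells; tissue cell content per 0.6 mg
lysate drawn log-uniform over a 30-fold span centred on the cell-line
count (only the 30× spleen-vs-heart spread is known; centring on the
cell-line count keeps the two classes comparable). Spike amounts are
titrated to ~1:1 against the median endogenous level, as a real
mastermix is.

What the generator does **not** emulate: chromatographic interference
and peak-integration error structure, correlated noise between
fragments of one peptide, compositional TPM constraints, cell-type
heterogeneity within tissues, and ploidy differences. A green test on
synthetic data therefore establishes that the *computational chain* is
correct and well-conditioned under the stated noise model — not that
the laboratory assumptions (histone constancy, clean proteotypic
peptides) hold in any particular experiment.

Determinism: every run is a pure function of (config, seed). One
top-level seed is fanned into named substreams (`truth`,
`measurements`, `cv`, …) via a fixed hash, so adding draws in one
module never shifts another module's stream.

## Numerical choices and degenerate inputs

* Unit conversion lives in exactly one place
  (`peptide_copies()`): copies/cell = ratio × fmol × 6.02214076e8
  molecules per fmol-quadrillionth / cells.
* A fragment with light signal but zero/absent heavy signal is
  *unusable*, tallied, never an exception; a peptide needs
  `min_fragments` (default 1) usable fragments.
* A histone anchor missing from a replicate is an error by default —
  silent renormalisation on three histones would bias that replicate —
  with an explicit `allow_missing_histones` override.
* Genes need `min_samples = 2` RTP values for a conversion factor and
  3 positive pairs for any correlation; below that, values are absent
  and tallied, not imputed.
* `pearson_test()` and `pooled_t_test()` are written as closed-form
  textbook statistics (t on n−2 df; Fisher-Z interval; pooled
  variance) precisely so the test suite can verify them against
  `stats::cor.test`/`t.test` as an independent route.
* With noise switched off the pipeline recovers ground truth to
  ~1e-15 relative error; the acceptance suite requires 1e-9, leaving
  six orders of margin for platform float differences.

## Known limitations

The quantifiability filter's default global mode mirrors whole-panel
curation: one failed sample removes the gene everywhere, which on
synthetic data with 2% dropouts removes ~a third of genes — stricter
than per-sample handling (`drop = "per_sample"`), which reuses all
remaining data. Tissue copy numbers are per *average* 2N-equivalent
cell across a mixed cell population. No shared-peptide apportionment
or modification-state correction is attempted; peptides are assumed
proteotypic and quantitative as given.
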