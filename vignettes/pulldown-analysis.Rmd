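---
title: "Calling miRNA targets from biotinylated-miRNA pull-down microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling miRNA targets from biotinylated-miRNA pull-down microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpulldown)
```

## The assay and its readout

A biotinylated miRNA mimic transfected into cells is captured on
streptavidin beads together with the mRNAs it binds. Profiling four sample
arms on expression arrays — the streptavidin **pull-down** and the cellular
**input**, each under transfection with the **test** miRNA and with a
**control** miRNA from a distant species — gives, per probe and biological
replicate, the enrichment ratio

$$
R \;=\; \frac{\mathrm{PD}_\mathrm{test} / \mathrm{PD}_\mathrm{control}}
             {\mathrm{input}_\mathrm{test} / \mathrm{input}_\mathrm{control}}.
$$

Dividing by the input fraction does two things at once: it cancels
nonspecific bead capture, which scales with cellular abundance and affects
both pull-down arms alike, and it folds any knockdown of the target's mRNA
into the denominator, sharpening the signal. Transcripts specifically
associated with the test miRNA have $R > 1$; everything else scatters
around 1 with array noise.

This package implements the downstream computation only: it consumes
normalized (e.g. RMA) probe-level matrices and produces hit calls,
down-regulation calls, cross-cell-line overlaps, positional seed-match
statistics and pathway over-representation. Raw-array processing,
present/absent calls and target-prediction algorithms are out of scope;
externally predicted target lists are consumed as plain gene lists.

## Hit calling on a log-normal background

Array intensities are multiplicative, so ratios of four of them are treated
as log-normal. The stage order is fixed and documented: ratio per probe per
replicate, arithmetic mean over replicates, then arithmetic mean over a
gene's probes (`average = "geometric"` switches both means to geometric).
The background is the full distribution of $\log_2$ mean ratios over
expressed genes — it must include any true targets, since the threshold is
defined from the whole distribution — summarized by its sample mean $\mu$
and sample SD $\sigma$ ($n-1$ denominator). A gene is a **hit** when its
mean ratio is at least $2^{\mu + k\sigma}$, boundary inclusive, with $k = 1$
by default. Thresholds are reported in both $\log_2$ and fold units and are
fitted independently per cell line, so each cell line gets its own fold
equivalent. Two open points were settled as follows: the SD is computed on
gene-level (not probe-level) log ratios, and the fit always uses the full
distribution including eventual hits.

Genes are kept only if at least one of their probes exceeds the
expression background in at least one sample. Arrays' native
present/absent calls are platform-specific, so the background here is a
reproducible surrogate: an absolute intensity or, by default, the 5th
percentile of the pooled intensity matrix. Genes with a zero or negative
intensity anywhere in their ratio terms are excluded outright with a logged
count — RMA output is strictly positive, so such values signal corrupt
input rather than biology, and pseudocounts would silently distort ratios.

Down-regulation uses the input arms alone: fold change
$\mathrm{input}_\mathrm{test}/\mathrm{input}_\mathrm{control}$, averaged and
collapsed in the same order, with genes reduced by at least 20%
(`mean_fc <= 0.8`, inclusive) called down. Gene-set fold-change
distributions are compared by two-sample Kolmogorov–Smirnov on $\log_2$
fold changes ($D$ is invariant under the monotone transform; the log scale
treats up and down symmetrically in the exported CDF tables). The statistic
is evaluated at all pooled data points, and the p-value is the asymptotic
Kolmogorov approximation with the standard effective sample size — the
comparisons of interest involve hundreds to thousands of genes, where exact
small-sample corrections are irrelevant.

## Positional hexamer analysis

Every 6-nt window of the mature miRNA (positions $1 \dots L-5$, 5′ to 3′)
defines a DNA target site: the reverse complement of the window with U→T.
For a gene set and region (5′UTR, CDS, 3′UTR) the statistic is the pooled
frequency — total exact matches across the set's sequences divided by total
kilobases — rather than a mean of per-gene frequencies; "matches per kb of
sequence" describes pooled sequence, and pooling keeps short UTRs from
dominating. Matches are counted overlapping (the conservative superset;
with a 6-mer the difference is negligible in practice), case-insensitively,
and positions containing N never match. When several transcripts map to one
gene, the transcript with the longest 3′UTR is retained at FASTA ingestion,
with ties broken lexicographically by transcript id so ingestion is
deterministic.

Significance comes from a Monte-Carlo null: `n_sims` random gene sets of
the same size drawn without replacement from the background (all expressed
genes, *including* the test set — excluding it would bias the null). The
two-tailed empirical p doubles the smaller one-sided tail, each with a +1
pseudocount:

$$
p = \min\!\Big(1,\; 2\min(P_{\ge}, P_{\le})\Big),
\qquad P_{\ge} = \frac{1 + \#\{F_\mathrm{null} \ge F_\mathrm{obs}\}}{n_\mathrm{sims}+1},
$$

so the attainable floor is $2/(n_\mathrm{sims}+1)$. When the empirical p
reaches $10^{-4}$ or its floor, a Gaussian is fitted to the null sample and
the two-tailed normal tail probability is reported *alongside* the
empirical value, never silently replacing it; a degenerate null (SD = 0)
yields NA with a warning. The Gaussian is justified by the null statistic
being a (ratio-normalized) sum over many genes; a gamma alternative was
considered and rejected as adding a shape parameter the null sample cannot
pin down at these depths.

## Pathway over-representation and the overlap network

For a query of $n$ genes in a universe of $N$, a pathway with $K$ genes in
the universe and $k$ in the query scores the inclusive hypergeometric upper
tail $P(X \ge k)$, computed via `phyper` (log-space internally). The
universe defaults to all expressed genes rather than all genes on the
platform — unexpressed genes can never enter a query, and counting them
deflates p-values; the choice is configurable. Significance is a raw
$p < 0.001$ filter, matching the analysis this pipeline reproduces; a
Benjamini–Hochberg column is emitted for information only. The network
keeps significant pathways as nodes (node size = $k$), optionally retaining
non-significant ones flagged for gray rendering, and draws an edge weighted
by the number of *query* genes shared between two pathways — the genes
driving the enrichment — with full-membership overlap behind a flag.

## What the synthetic generator emulates

`simulation_config()` fixes the study conditions; `simulate_expression()`,
`simulate_sequences()` and `simulate_pathways()` generate a complete study
from them, byte-reproducibly given `rng_seed`.

* **Expression.** Baseline abundance per gene is log-normal
  ($\log_2$ mean 7, SD 2, a typical post-RMA dynamic range). Expected arm
  levels for a gene with abundance $a$, planted knockdown $kd$ and
  enrichment $e$ (both 1 for non-targets) are $\mathrm{input}_c = a$,
  $\mathrm{input}_t = kd\,a$, $\mathrm{PD}_c = b$,
  $\mathrm{PD}_t = e\,kd\,b$, where $b = a^{\beta}$ is the
  abundance-coupled bead capture common to both pull-down arms
  ($\beta$ = `background_affinity`, default 1). The enrichment ratio's
  expectation is therefore exactly $e$ — input normalization cancels the
  bead background by construction, which is the property the assay design
  claims. Per-probe affinity multipliers ($\log_2$ SD 0.25) are constant
  across samples and cancel in every ratio; replicate noise is Gaussian on
  the $\log_2$ scale (SD 0.5 per measurement by default) and exponentiated,
  giving the log-normal background the hit calling assumes.
* **Defaults as study conditions.** 2000 genes, 1–3 probes per gene, 2
  replicates per arm, 10% targets, 4-fold enrichment, knockdown to 70%.
  The array platform's true noise magnitude is not derivable from the
  analysis being reproduced; 0.5 on $\log_2$ is a mid-range value for
  two-replicate array designs and is stated here once, not tuned.
* **Sequences.** Region lengths are log-normal (defaults: 5′UTR ≈ 200 bp,
  CDS ≈ 1.3 kb, 3′UTR ≈ 1 kb medians); composition is uniform A/C/G/T
  outside planted sites. Seed sites (reverse complement of miRNA nt 2–7)
  are planted in 3′UTRs as a Poisson process — 5/kb in targets, 1/kb
  otherwise — with rejection sampling so planted sites never overlap and
  recorded counts are exact.
* **Pathways.** A configurable fraction of pathways oversamples target
  genes at 8:1 weight, making hypergeometric recovery possible; the rest
  sample uniformly and serve as the calibration null.

What it does **not** emulate: probe-level cross-hybridization, correlated
(batch) noise across samples, GC or repeat structure in sequences,
translation-only repression, or any sequence conservation signal. Tests
passing on these simulations therefore validate the statistical machinery
and its calibration, not the biological error rates on real arrays.

## Numerical and testing choices

* Log base 2 throughout; thresholds reported in fold and $\log_2$ units.
* All readers tolerate CRLF and `#` comment lines; writers emit
  deterministic row order so identical seeds give identical bytes.
* Monte-Carlo draws come from one seeded RNG stream over a fixed iteration
  order (set, region, window), so the full scan grid is reproducible.
* The closed-form recovery oracle used in the test suite treats per-gene
  $\log_2$ ratios as normal. That is exact under geometric replicate
  averaging, so the parameter-recovery check runs the stage with the
  geometric switch; under the default arithmetic mean the log of a
  lognormal mean has a small (~2%) tail-shape bias relative to its
  Fenton–Wilkinson normal approximation, which would blur what the check
  measures. The arithmetic path is pinned separately by exact equality
  with a spreadsheet-style oracle (1e-12) and by the null hit-rate tail
  (15.9% expected at 1 SD).
* Calibration checks use problem sizes chosen to make Monte-Carlo error
  small relative to the effects tested: 20 null simulations of 10,000
  genes for the hit-rate tail; 1000 random query sets (999 draws each)
  for p-value uniformity; 100 seeded runs for seed-window detection;
  exhaustive enumeration up to a universe of 12 for the hypergeometric
  tail.

## Limitations

The pipeline consumes normalized matrices and inherits whatever biases
normalization leaves. The SD-threshold hit rule is a calibrated outlier
rule, not a per-gene test — it controls no FDR and is reported as such.
The asymptotic KS p is anticonservative below a few dozen genes per set
(such sets are skipped). Tail-extrapolated p-values far beyond the
Monte-Carlo floor depend on the Gaussian fit of the null and should be
read as orders of magnitude, not exact probabilities.
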