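# mirpulldown

Analysis pipeline for **biotinylated-miRNA pull-down** experiments read out
on expression microarrays — the biochemical route to direct miRNA target
identification: transfect a 3′-biotinylated miRNA mimic, capture the mRNAs
bound to it on streptavidin beads, and profile the pull-down against the
cellular input under both the test miRNA and a control miRNA.

It is written for computational biologists analysing such four-arm designs
(pull-down/input × test/control miRNA, with replicates, typically in more
than one cell line), and ships a synthetic-data generator with planted
ground truth so the entire pipeline runs and is testable without any
external download.

## What it computes

For each gene, the **enrichment ratio**

```
R = (PD_test / PD_control) / (input_test / input_control)
```

is computed per probe and replicate, averaged over replicates, and averaged
over each gene's probes. Normalizing to input cancels abundance-driven
nonspecific bead capture and folds target knockdown into the denominator.
Hits are genes whose mean ratio lies ≥ 1 SD above the mean of a log-normal
background fitted to all expressed genes' log2 ratios (threshold reported
as a fold equivalent, fitted independently per cell line); hit sets from
two cell lines are intersected. From the input arms alone, genes whose
mRNA fell by ≥ 20% (fold change ≤ 0.8) are called down-regulated, and
fold-change distributions of gene sets are compared by CDFs and the
two-sample Kolmogorov–Smirnov test. Every 6-nt window of the mature miRNA
is scanned against 5′UTR/CDS/3′UTR sequences as its reverse-complement DNA
site; per-kb pooled match frequencies get two-tailed empirical p-values
from Monte-Carlo resampling of equally sized random gene sets, with
Gaussian tail extrapolation when the empirical p reaches its floor.
Finally, gene sets are tested for pathway over-representation with the
hypergeometric upper tail, and pathways significant at p < 0.001 are
exported as an overlap network (SIF + node attributes).

## Worked example

The numbered scripts under `analysis/` run a complete synthetic
two-cell-line study (2000 genes, 10% planted targets shared between cell
lines, 4× pull-down enrichment, knockdown to 70%, seed sites at 5/kb in
target 3′UTRs vs 1/kb background):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_enrichment.R
Rscript analysis/03_downregulation.R
Rscript analysis/04_hexamer.R
Rscript analysis/05_pathways.R
```

which prints, along the way (tables land under `results/`):

```
CL1: 1970 expressed genes; 1 SD threshold = 2.41-fold; 255 hits
CL2: 1964 expressed genes; 1 SD threshold = 2.43-fold; 254 hits
overlap: 183 genes hit in both cell lines (72 only CL1, 71 only CL2)
of the overlap, 98% are planted targets
...
CL2: 46% of down-regulated genes were also pulled down
  KS down_CL2 vs expressed_CL2: D = 0.824, p = 0
...
overlap 3'UTR: seed window (nt 2-7, ACTGCC) fold 3.12 (p_emp 0.002, tail p 1.9e-141); top window starts at nt 2
...
overlap: 8/50 pathways significant at p < 0.001; network 8 nodes, 27 edges; top: PW004 (p = 3.5e-27)
```

Read: hit calling at 1 SD above the log-normal background lands at a
~2.4-fold threshold and recovers the planted targets with high purity in
the cross-cell-line overlap; down-regulated genes are strongly shifted in
fold change (KS D = 0.82 against all expressed genes); the miRNA seed
window (nt 2–7, DNA site ACTGCC) is the most enriched of all positional
hexamer windows in 3′UTRs, as planted; and the target-enriched pathways
surface at p < 0.001 and connect through shared query genes.

The same pipeline runs on real data by pointing a YAML config (see
`?validate_config`) at your matrices, region FASTA and GMT files and
calling `run_all()`.

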