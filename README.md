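# neuromir

miRNA expression profiling of regionalized human neural progenitors and
miR-10 target inference — an R analysis pipeline with a fully simulatable
test bed.

## What it does, and for whom

During early neural development, progenitors acquire forebrain (FB),
midbrain (MB) or hindbrain (HB) identity, and microRNAs show strongly
region-specific expression — the miR-10 family in particular is a marker
of posterior (hindbrain/spinal cord) identity and can make up a third or
more of the entire miRNA pool there. `neuromir` is for computational
biologists analysing this kind of experiment end to end:

* **Small-RNA counting**: FASTQ → mature-miRNA count matrix by adapter
  trimming, ≥15 nt length filtering, collapsing of identical reads and
  exact-match assignment to a miRBase-style mature reference (identical
  mature sequences merged into one feature).
* **Profiling**: equal-total normalization; selection of
  progenitor-enriched miRNAs with fold change
  FC = (mean_group + c) / (mean_hESC + c) ≥ 4 in at least one
  neuroepithelial group; miRNA-family pool fractions; hierarchical sample
  clustering (log2, 1 − Pearson r, average linkage).
* **Targeted qPCR panels**: dCq normalization
  (dCq = mean Cq over the common assay set − Cq, per sample), top-SD
  assay selection, per-miRNA one-way ANOVA across foetal age groups,
  centred group profiles, detection calls, and ΔΔCt relative
  quantification (RQ = 2^(−ΔΔCt)).
* **Target inference**: per-gene fold changes after inducible miRNA
  overexpression, a two-sample Kolmogorov–Smirnov test for a left shift
  of the predicted targets' log2-FC cumulative distribution against all
  other expressed genes (mean control count > 10 reads), and the
  high-confidence target set = predicted targets downregulated (FC < 1)
  in **both** overexpression arms.
* **Synthetic data**: generators for reads, grouped miRNA count matrices
  (negative-binomial noise, seeded regional family signatures and
  enrichment), Cq panels with region/age structure, and paired
  overexpression/control mRNA experiments with seeded repression — each
  returning the ground truth needed to score the pipeline.

## Worked example

Simulate a doxycycline-inducible miR-10a/miR-10b overexpression
experiment (12,000 genes, 2 arms × dox/control × 3 replicates, 90 true
targets repressed by 2^−0.6, 90 decoy predicted targets) and infer
targets:

```r
library(neuromir)
sim <- simulate_mrna_overexpression(seed = 1)
res <- infer_targets(sim$expr, sim$truth$predicted)
res
#> miRNA target inference by fold-change CDF shift
#> expressed genes: 10398; predicted targets expressed: 160
#>   miR10a: KS D = 0.306, p = 3.06e-13, shift left; 111/160 targets down (FC < 1)
#>   miR10b: KS D = 0.342, p = 2.22e-16, shift left; 119/160 targets down (FC < 1)
#> high-confidence targets (down in both arms): 93
```

Reading the output: of 12,000 simulated genes, 10,398 pass the >10-read
expressed filter; 160 of the 180 predicted targets are expressed. In both
arms the targets' fold-change CDF is shifted strongly left of the
background (KS D ≈ 0.31–0.34, p ≪ 0.0001), and 93 predicted targets are
downregulated under both miR-10a and miR-10b induction — the
high-confidence set (here containing 71 of the 79 expressed true targets).

A command-line front end over the same functions is installed at
`system.file("cli", "neuromir", package = "neuromir")` with subcommands
`count`, `normalize`, `enrich`, `families`, `cluster`, `dcq`, `anova`,
`profiles`, `ddct` and `targets`.

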