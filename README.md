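# mirnetevo

Systems-level analysis of microRNA evolution in a signed human
TF–miRNA regulatory network.

Transcription factors (TFs) regulate genes and miRNA genes with
activating or repressing signals; miRNAs repress their targets
post-transcriptionally. Together they form a directed, signed,
tri-partite network (TF-gene, TF-miRNA, miRNA-target edges). This
package implements the statistical pipeline for asking how that
architecture shapes molecular evolution, for researchers working with
curated regulatory maps and evolutionary-rate data:

* **Sign-stratified coevolution** — Spearman rank correlation *R* of
  regulator and partner evolutionary rates (protein dN; miRNA sequence
  divergence in substitutions per aligned site), computed separately
  for activating and repressing edges, plus median-split Wilcoxon
  comparisons.
* **Signal preference** — a 2×2 Fisher exact test of whether rapidly
  evolving TFs preferentially activate rather than repress miRNAs.
* **Pathway co-regulation** — per-pair common-pathway membership,
  activating vs repressing pairs, summarised by the sample odds ratio
  OR = (a·d)/(b·c) and Fisher's exact test (probability-mass two-sided
  convention).
* **Cascade ordering** — upstream/downstream regulator pairs from
  directed reachability (Dijkstra/BFS over unit weights), and the
  fraction of pairs whose upstream member evolves more slowly.
* **Sensitivity analysis** — every statistic re-run on replicates with
  5% of links removed and 5% spurious links added.
* **miRNA divergence estimation** from pairwise genome-alignment
  blocks (AXT) over miRNA coordinates (BED): substitutions per aligned
  site, gap columns excluded from numerator and denominator.
* **A synthetic-data generator** that emulates the curated network's
  statistical structure (skewed out-degree, ~79% activating TF edges,
  all-repressive miRNA edges, sign-dependent coevolution, opposite
  cascade gradients, pathway co-membership enrichment) with known
  planted parameters, so the whole pipeline is testable end to end.

## Worked example

The `analysis/` directory holds the numbered drivers of the full
workflow (`01_simulate.R` … `07_sensitivity.R`). They generate a
study-condition synthetic bundle under `results/data/` and write one
table per analysis under `results/`. Running them in order prints,
among other things (seed 42):

```
Signed regulatory network: 1997 nodes (181 TF, 141 miRNA, 1675 gene), 4298 edges
Computed divergence for 141/141 miRNAs (median 0.051)
TF-activation-miRNA pairs (n=164): rho = 0.182 (p = 0.0195);
    miRNA medians 0.038 vs 0.051 by TF-rate half (p = 0.0482)
TF-repression-miRNA pairs (n=46): rho = -0.014 (p = 0.929)
miRNA-target pairs (n=1433): target dN medians 0.059 (conserved-miRNA half)
    vs 0.049 (fast-miRNA half), p = 3.32e-07
Cascade pairs (TF): 396 pairs; upstream lower in 258 (65.2%)
Cascade pairs (miRNA): 173 pairs; upstream lower in 83 (49.1%)
```

Read: miRNA rates coevolve with their *activators* (R = 0.18,
significant) but not their repressors (R ≈ 0, n.s.); slowly evolving
miRNAs regulate rapidly evolving targets (median dN 0.059 vs 0.049);
and upstream TFs are more conserved than downstream TFs while miRNAs
do not share that polarity — all of which are the planted properties
of the generated data, recovered by the pipeline.

The same computation is available as one call:

```r
library(mirnetevo)
res <- run_full_analysis(list(
  network = "results/data/network.tsv",
  protein_rates = "results/data/protein_rates.tsv",
  alignments = "results/data/alignments.axt",
  mirna_bed = "results/data/mirna.bed",
  pathways = "results/data/pathways.gmt",
  expression = "results/data/expression.tsv",
  out_dir = "results/full", seed = 42))
```

which writes one TSV per analysis plus a machine-readable
`summary.json`, and is deterministic in (inputs, seed).

## Layout

```
R/                  package code: network model, statistics, divergence,
                    coevolution, pathways, cascade, sensitivity, generator,
                    pipeline orchestration
analysis/           numbered workflow drivers (thin wrappers over R/)
scripts/            acceptance script
tests/testthat/     unit, property and acceptance tests with
                    enumeration oracles
vignettes/          the methods vignette (model, conventions, design)
```
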