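---
title: "Methods: miRNA evolution in a signed TF-miRNA regulatory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA evolution in a signed TF-miRNA regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnetevo)
```

## The model

Transcription factors (TFs) and microRNAs (miRNAs) are the two main
classes of human gene regulators. TFs act transcriptionally and can
either activate or repress their targets, including miRNA genes;
miRNAs act post-transcriptionally and, as far as experimentally
supported interactions go, always repress. Together with their target
genes they form a directed, signed, tri-partite regulatory network
with three edge types: TF-gene, TF-miRNA and miRNA-target.

The package asks how the architecture of this network constrains
molecular evolution. Each node carries an evolutionary rate: for
proteins the non-synonymous substitution rate dN, for miRNAs the
sequence divergence between two primate genomes, measured as the
per-aligned-site substitution proportion over the miRNA's genomic
interval. The analyses are:

* **Sign-stratified coevolution.** Across regulator-partner edges of
  one type, the Spearman rank correlation of the two endpoint rates,
  computed separately for activating and repressing edges. A positive
  correlation on activating TF-miRNA edges with a null correlation on
  repressing edges is the headline pattern: a miRNA that is switched
  on by its TF works alongside it and the two adapt together; a miRNA
  that is repressed by a TF does not function with it, so there is no
  coupling to maintain.
* **Median-split comparisons.** Edges are sorted by one member's rate
  and split into equal halves; the other member's rates in the two
  halves are compared by a Wilcoxon rank-sum test. Applied to
  TF-miRNA edges (split on the TF) and miRNA-target edges (split on
  the miRNA, where the planted expectation is inverted: conserved
  miRNAs regulate rapidly evolving targets).
* **Signal preference.** The same split on TF rate, but counting
  activation versus repression signals per half in a 2x2 table with
  Fisher's exact test: do rapidly evolving TFs preferentially activate
  miRNAs?
* **Pathway co-regulation.** For each signed TF-miRNA pair, whether
  some signaling pathway contains both members; activating versus
  repressing pairs give a 2x2 table, summarised by the sample odds
  ratio and Fisher's exact test.
* **Cascade ordering.** Within a regulator class, node A is upstream
  of node B when a directed path A to B exists and no return path
  exists. Across such ordered pairs, the fraction in which the
  upstream node has the strictly lower rate measures the polarity of
  evolutionary rates along the regulatory cascade; TFs and miRNAs are
  expected to show opposite polarity.
* **Sensitivity analysis.** All of the above re-run on replicates in
  which 5% of links are removed and 5% spurious class-compatible links
  are added, emulating the incompleteness of curated networks.

## Statistical conventions

Several of these tests have more than one "standard" two-sided
definition, so the package pins one of each and tests it against
brute-force enumeration oracles:

* **Fisher's exact test** uses the probability-mass rule: the
  two-sided p is the sum of hypergeometric probabilities, over tables
  with the observed margins, that do not exceed the probability of the
  observed table. The reported odds ratio is the *sample* odds ratio
  `(a*d)/(b*c)`, not the conditional maximum-likelihood estimate;
  only the sample OR reproduces printed values such as 1.94 from the
  (349, 1327, 121, 893) co-regulation table. `b*c == 0` gives an
  infinite OR; a fully degenerate column gives an undefined one.
* **Wilcoxon rank-sum** is exact (full enumeration of the rank-sum
  distribution) when the pooled sample has at most 12 observations and
  no ties, and a tie-corrected normal approximation without continuity
  correction otherwise. A pooled sample that is entirely tied carries
  no evidence and reports p = 1 rather than a 0/0.
* **Spearman correlation** uses mid-ranks for ties. The p-value is the
  exact permutation p for n of at most 9 without ties and the
  t-approximation otherwise. The exact regime stops at 9 rather than
  10 because the underlying exact null distribution is a true
  enumeration only up to n = 9; beyond that the available "exact"
  path is itself an Edgeworth series, which we consider dishonest to
  label exact. Constant input leaves the coefficient undefined and is
  reported as such.

p-values are delegated to R's `fisher.test`, `wilcox.test` and
`cor.test` machinery where it implements exactly these conventions;
the test suite checks every one of them against independent
enumeration code (all 2x2 tables with small entries and random tables
with N up to 40; every group-size split with up to 12 observations;
full permutation enumeration for small n) at 1e-12. No
multiple-testing correction is applied anywhere, deliberately.

## Divergence estimation

`mirna_divergence()` scans pairwise alignment blocks (AXT input) over
a miRNA's genomic interval (BED input, 0-based half-open internally).
Columns with a gap in either species are excluded from both numerator
and denominator; of the remaining columns, the case-insensitive
mismatch fraction is the divergence. Choices worth knowing:

* **No multiple-hit correction by default.** At primate-scale
  distances (around 0.05 substitutions per site) the raw proportion
  and the Jukes-Cantor correction differ by under 4%, and observed
  medians in this regime are conventionally quoted as raw
  proportions. A `jukes_cantor` switch exists, off by default.
* **Coverage.** An interval whose aligned-site fraction falls below
  `min_fraction` (default 0.5) is flagged `low_coverage` and excluded
  from analyses; an interval with no overlapping block is flagged
  `no_alignment`. The 0.5 threshold is our choice; partially aligned
  miRNAs are a real phenomenon and silently averaging over 10 aligned
  sites would be worse than excluding.
* **Overlapping blocks.** The first block covering a reference
  position wins, with a warning. Best-chain pairwise alignments are
  non-overlapping, so this matters only for malformed input.
* Strand is irrelevant to a substitution count, so divergence is
  invariant under reverse-complementing both sequences together with a
  strand flip; the suite asserts this.

## Network and cascade conventions

* Node classes are inferred from edge context (sources of TF-* edges
  are TFs, miRNA-target sources and TF-miRNA targets are miRNAs,
  everything else is a gene) because curated source tables are
  relation lists, not node lists. An id implied to be both TF and
  miRNA is a hard error. TF targets are accepted under TF-gene edges;
  without them TF cascades could not exist.
* Duplicate (source, target, type) triples are rejected even with
  agreeing signs; a conflicting duplicate would silently corrupt every
  sign-stratified analysis downstream.
* Components are weakly connected (direction ignored), matching the
  "single interconnected network" reading of a regulatory map.
* Shortest paths use unit weights, where Dijkstra's algorithm and
  breadth-first search coincide; the suite asserts the equivalence
  against a BFS oracle.
* Upstream/downstream uses directed reachability over *all* edge
  types. Mutually reachable pairs are excluded rather than counted in
  both orientations; with no stated convention for cycles, exclusion
  is the conservative choice. Rate ties are excluded from the
  fraction's denominator because "lower rate" is strict.
* In the median split, an odd group puts its middle element in the
  low half, and boundary ties are broken lexicographically by edge id,
  so the split is deterministic.
* Each *edge* is one observation in the coevolution correlations. A
  hub TF with k miRNA partners contributes k pairs sharing one rate;
  this pseudo-replication matches the "pairs" framing of the analyses
  but means the effective sample size is smaller than the pair count.
  The synthetic recovery experiments quantify exactly this attenuation
  (see below).

## Pathway counting units

The co-regulation analysis supports two units. With `pair` (default)
each signed TF-miRNA pair is one observation and the outcome is
whether any pathway contains both members. With `pair_pathway` each
(pair, pathway-regulated-by-either-member) combination is one
observation. Both exist because published contingency totals in this
analysis family can exceed the number of distinct TF-miRNA links,
implying a per-pair-per-pathway unit without saying so; rather than
guess, the package implements both and reports which was used.

## The synthetic-data generator

`synthetic_config()` + the `generate_*()` functions produce networks,
rates, pathways, expression matrices and alignment blocks with planted
structure, so that every pipeline stage has a ground truth.

**Planting mechanism.** Every node receives a standard-normal latent.
A partner's latent blends the scaled sum of its regulators' latents
with fresh noise (a Gaussian-copula construction); all latents then
pass through a monotone lognormal quantile transform into rates, so
rank correlations planted on the latent scale survive exactly.
Because hub regulators duplicate one latent across many edges, the
pooled edge-level Spearman correlation is attenuated below the
per-edge value; the generator therefore *calibrates* its blend
coefficient by bisection against a small Monte-Carlo estimate of the
realized pooled correlation under the actual topology (including any
cascade gradient), and reaches the requested value whenever it is
attainable at all.

**Cascade depth.** Gradients shift latents per unit of depth, where
depth is a longest-path potential from the root regulators computed on
the condensation of the graph (strongly connected components
collapsed). A longest-path potential increases along every edge, so it
is consistent with the upstream/downstream ordering the cascade
analysis measures; a min-distance-from-roots depth is not (a node far
down one cascade can sit at depth 1 via another root) and a planted
gradient expressed in it proved unrecoverable in exactly the way that
argument predicts.

**Alignments.** Blocks are i.i.d. per-site substitutions at each
interval's planted rate (plus occasional query-gap columns), so the
divergence stage re-estimates the planted miRNA rates with binomial
noise of roughly 0.024 at 80 sites - the same noise real short-interval
divergence estimates carry.

**Defaults are the study conditions.** The default configuration
reproduces the composition and observed effect sizes of the curated
human TF-miRNA network this package is designed around: 425/150/1700
nodes; 2655/210/1433 edges; 79% activating TF edges; a planted
activating coevolution of 0.25 that measures as roughly 0.15-0.19
after alignment noise; a TF-gene coevolution of 0.1; a miRNA-target
association of -0.2; cascade gradients +0.12/-0.15 giving
upstream-lower fractions of about 0.63 for TFs and 0.3-0.5 for miRNAs;
a pathway odds ratio of 2.0 over 183 pathways with a 12% repressing
baseline. Node counts are nominal: regulators that never get sampled
as an edge source do not materialise, so a default network has about
180 realised TFs.

**What the generator does not emulate:** real sequence content (i.i.d.
substitutions only), tissue expression covariance (each TF profile is
independent noise), pathway size distributions, sign-rate association
(signal preference is null under the defaults), and any correlation
between a node's degree and its rate. Passing tests on synthetic data
therefore validate the estimators and the pipeline plumbing, not any
biological claim about real networks.

## Recovery-experiment design

The acceptance surface of the package is parameter recovery: each
planted parameter must be recovered by the corresponding pipeline
stage within a pre-registered band. Three design rules keep these
experiments interpretable, and all were fixed while designing the
experiments:

* **Single factor.** Each experiment plants only the parameter under
  study; every other planted effect is at its null. Under the full
  defaults the effects interact (a strong coevolution channel
  propagates the TF cascade gradient into miRNA rates), which is
  realistic but confounds recovery bands.
* **Near-independent pairs** for the correlation experiment (degree
  skew 0.8, regulator counts comparable to edge counts, about 200
  pairs per stratum): under heavy hub duplication the pooled Spearman
  estimator is attenuated and high-variance, and a recovery band would
  test the topology, not the estimator.
* **Pathway count scaled with links** (the default ratio of 183
  pathways per 210 links) for the odds-ratio experiment at 2200
  links: holding 183 pathways fixed while scaling links up tenfold
  creates accidental co-memberships through hub placements that bias
  the measured OR toward 1.
* Significance in the stratified-coevolution recovery is judged at
  p < 0.01 on both strata: the activating stratum must clear it and
  the repressing stratum must not. Using one level on both sides keeps
  the 20-seed pass criterion meaningful (at a 0.05 level a perfect
  null already fails a 18-of-20 criterion about 7% of the time).

## Problem sizes

Unit tests run networks of tens to hundreds of edges; the recovery
experiments use 20 seeded replicates at 400-2300 edges; the
divergence-convergence check uses 1,000 intervals of 80 sites; the
sensitivity checks use 20 replicates of 5%/5% perturbation on networks
of about 500 edges. The `analysis/` drivers and the acceptance script
run the full default composition (4,298 edges). These sizes are where
the bands above have the power the experiments need; everything scales
up by changing the config.

## Known limitations

* The latent-blend calibration targets the pooled correlation in
  expectation; an individual seed still varies by roughly `1/sqrt(n)`.
* When planted effects conflict (strong coevolution against an
  opposing gradient), the calibration saturates at its coefficient cap
  and the realized correlation falls short of the request; the
  manifest records the request, not the realization.
* Sign inference from expression uses the bare sign of a Spearman
  correlation with no significance filter (a `min_abs_rho` threshold
  is available); on short profiles this misclassifies weakly coupled
  pairs in both directions.
* The sample odds ratio is reported without a confidence interval;
  the sensitivity machinery, not an asymptotic interval, is the
  package's statement about stability.
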