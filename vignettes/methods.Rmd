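---
title: "Models, parameters and design choices in mirstem"
author: "mirstem authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in mirstem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirstem` re-implements the computational arc of a multiplexed small-RNA
sequencing study of embryonic stem cell lines: read filtering, genome
mapping, hierarchical annotation, known- and novel-miRNA quantification,
expression-consistency statistics, miRNA–target network analysis against
evolutionary rate, and cross-species comparison. This vignette records
the models behind each stage, the tunable parameters with their defaults
and rationale, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely open.

## The synthetic study and what it emulates

The generator (`simulationConfig()`, `simulateStudy()`) defines the study
conditions under which everything is tested:

* **Three libraries of 10^5 reads** of fixed 35 nt: a 6 nt multiplex
  index, an 18–23 nt insert, and a 3' adapter fill. Inserts shorter than
  the read leave at least six adapter bases, so exact-prefix trimming is
  always decidable.
* **Read-category composition** 60 % known miRNA, 6 % structural ncRNA
  (rRNA/tRNA/scRNA/snRNA/snoRNA), 3 % each repeat/exon/intron, 25 %
  unannotated. The unannotated pool is split between mature products of
  *withheld* (novel) precursors (30 %) and uniform intergenic fragments
  (70 %), which both exercises novel-miRNA discovery and supports the
  Poisson background-threshold stage.
* **A 4 × 700 kb genome** of uniform-random DNA. Annotation intervals
  occupy the first ~40 % of each chromosome, non-overlapping within and
  across categories so that composition recovery is identifiable; 28
  hairpin precursors are planted in the remainder — two clusters of three
  within 5 kb gaps, all other loci ≥ 50 kb apart. At this size exact
  dictionary mapping of ~10^5 distinct tags takes seconds, and every
  pipeline property that matters (thresholds, clustering, recovery
  rates) is already exercised at full strength.
* **Planted hairpins**: an 8 nt lower stem, a 21–23 nt mature arm, a
  6–12 nt loop and the reverse-complemented arm with 0–2 mismatches —
  at least 19 Watson–Crick pairs, so any folding engine recovers a
  single hairpin. Arm length is tied to abundance rank (dominant species
  22–23 nt) so the clean-read length mode lands at 22–23 nt, as in real
  ESC libraries, even though the per-miRNA abundances are heavy-tailed.
* **Abundances** are log-normal (log10 SD 1.0 by default), spanning
  several orders of magnitude as real miRNA counts do; between-library
  variation is multiplicative log-normal noise (SD 0.15), giving the
  high concordance seen between lines derived under one protocol.
  Per-category read counts per library are multinomial, so category
  totals sum to the depth exactly and recovery checks can be exact.

Not emulated, deliberately: sequencing error, quality-score realism, PCR
duplication, isomiR end-heterogeneity, paralogous precursor families and
genome repeat structure. Passing recovery tests therefore demonstrate
correctness of the analysis logic under clean signal, not robustness to
base-calling noise; the mismatch-tolerant matching mode
(`quantifyKnown(maxMismatch = 1)`) exists but is off by default because
the simulator emits exact reads.

## Filtering and annotation

Adapter trimming is exact-prefix: the insert ends at the leftmost
occurrence of the adapter's first six bases. The "low-quality" filter is
implemented as *no non-ACGT bases*, since simulated qualities are
constant; a contaminant blocklist exists and defaults to empty. Clean
tags are 18–30 nt. Every raw read is accounted for: raw = clean + the
per-reason discard histogram, exactly.

Category conflicts among a tag's genomic hits resolve by the fixed
priority rRNA/tRNA/scRNA/snRNA/snoRNA (Genbank source beating Rfam) >
known miRNA > repeat > exon > intron, applied over **all** hits of a
multi-mapping tag; no overlap anywhere means "unann". Overlap is
strand-aware for the structural ncRNA tier and miRNA loci, strand-blind
for repeat/exon/intron. Interfaces use 1-based inclusive coordinates
(GFF convention); internal arithmetic converts explicitly.

Known-miRNA counting matches tags into precursor sequences: an exact
occurrence whose start lies within ±4 nt of an annotated mature arm adds
the tag's count to that mature product; loop-only matches do not count;
a tag matching k precursors adds to each (an explicit multi-counting
rule; fractional allocation is a possible extension, not a default).

## Novel miRNA discovery

Unannotated same-strand tags within 200 nt merge into candidate loci.
Loci are support-gated **before** folding: the mature (highest-count)
tag must reach `minReads = 30` in every library. Without this gate the
uniform intergenic background merges into kilobase-scale loci whose
folding is meaningless and expensive; read-support gating before
structure evaluation is also how the classical predictors behave.

Each surviving locus yields two 200 nt windows (tag as 5' arm: 20 nt
upstream / 160 nt downstream; tag as 3' arm: mirrored; minus-strand loci
reverse-complemented). Score-maximizing folding of the *whole* window
almost always pairs the random flanks into extra loops, so a planted
hairpin would fail a single-hairpin criterion evaluated on the raw
window. The pipeline therefore folds twice: the full window once to find
the pairing partners of the mature tag, then the enclosing span (±4 nt)
excised and refolded in isolation, and the hairpin criteria applied to
that span. The criteria themselves are:

* exactly one terminal loop, 3–20 nt;
* the mature tag entirely on one arm with ≥ 14 bases paired to the
  opposite arm;
* energy estimate ≤ −18 kcal/mol, where energy is −0.9 × the DP score
  (pair scores GC = 3, AU = 2, GU = 1, +1 per stacked pair, minimum
  loop 3). The DP is an O(n³) two-matrix recursion (best score with the
  ends paired / unconstrained) with deterministic traceback; its scores
  are verified against exhaustive enumeration of all nested structures
  on short windows. A 2 nt Dicer-like star offset is reported but not
  required.

The −18 kcal/mol and ≥ 14-paired-bases values are stand-ins at the scale
of classical predictor defaults, and both are arguments. Dinucleotide-
shuffled windows (random Eulerian walk on the transition multigraph)
pass these criteria at under 2 %, while planted hairpins supported by
≥ 30 reads/library are recovered essentially completely.

Called products whose passing precursor windows overlap are grouped into
one precursor (this also merges the strand mirror-image calls that
near-palindromic hairpins produce). The shared-call filter is
*inclusive*: a mature product with exactly 30 reads in each library
passes, which is the only reading consistent with the packaged reference
table of novel rESC miRNAs (rows with a count of exactly 30 are listed
as shared; the table's one doubly-located name counts as one precursor,
giving the 23-mature / 19-precursor tally the filters reproduce).

## Expression statistics

* `poissonThreshold()`: smallest integer T with `P(X ≥ T) < α`,
  `X ~ Poisson(λ)`, α = 10⁻⁴; λ analytic (reads × window / genome) or
  estimated as the mean count over randomly placed 50 bp bins (210,000
  by default, i.e. 10,000 per chromosome of a 21-chromosome genome —
  a default, not hard-coded, since synthetic genomes differ). Both modes
  are exposed; for a uniform background the analytic λ is small and the
  resulting thresholds are far below 30 reads, so how the historical
  30-read cutoff was tied to p < 10⁻⁴ is not reconstructible from the
  uniform model — the package exposes the machinery without claiming to
  reproduce that number.
* Clusters: per-chromosome chains of loci with inter-locus gap ≤ 10 kb
  (inclusive).
* `Var` := Jensen–Shannon divergence (log base 2) between the member-
  count proportions of a cluster in two libraries, pseudocount 0.5 per
  member; symmetric, in [0, 1] bits, 0 iff the proportions agree. `C.V.`
  := sample SD / mean of the per-library cluster RPM totals. `D.I.` :=
  (x − row mean)/row mean on the RPM matrix; rows sum to zero exactly.
  κ := Cohen's kappa on expressed/not calls at 30 absolute reads, with
  `Z = κ / √(Pₑ/(N(1−Pₑ)))`. These four are implementations of verbal
  descriptions (the defining formulas were not available), chosen as the
  standard statistic matching each description; they are stand-ins and
  are documented as such.

## Target prediction and the MT network

Seed sites follow the canonical types: the reverse complement of miRNA
positions 2–8 in the UTR is 7mer-m8, with a following A it is 8mer, the
reverse complement of 2–7 plus A is 7mer-A1; every occurrence is
reported and each 6-mer core is classified by its best supported type.
Conservation: the same site type at the aligned position (±2 alignment
columns, to absorb gap-induced shifts) in ≥ 4 of the species present.
Energy-based prediction (PITA/miRanda-style) is intentionally absent; an
import path for external prediction tables covers it.

Network: distinct (miRNA, gene) pairs are edges; a gene's degree is the
number of miRNAs targeting it. The degree–dN/dS analysis groups genes by
rounded degree (optionally normalized per 1 or 2 kb of 3'UTR), drops
bins with fewer than 10 genes, and correlates bin degree with bin mean
dN/dS (Pearson, two-sided t, df = bins − 2). Binning is a design choice:
the historical correlation/p pair implies ~17 aggregate points rather
than thousands of genes, and per-degree bins with an occupancy floor are
the natural aggregation; the raw per-gene correlation is available
behind `binned = FALSE`.

The generator's target tables draw per-gene degrees **uniformly** on
1..(2·meanDegree − 1). An earlier Poisson draft produced small
high-leverage tail bins whose noisy means structurally inflated the
binned test's type-I error to ~9 %; uniform degrees balance bin
occupancy and restore nominal calibration (~5 % measured over 400
seeds), which is the behaviour the analysis assumes of its input.

The randomization null adapts preferential attachment to a bipartite
graph: nodes arrive in random order, each attaching to one existing
opposite-side node with probability ∝ degree + 1 (the +1 lets isolated
nodes attach), then degree-proportional endpoint sampling adds distinct
edges up to the exact edge count. With node and edge counts matched to a
planted network the mean degrees are forced equal, so pooled or
gene-side rank tests barely discriminate; the miRNA side carries the
shape difference (concentrated planted degrees vs the null's skewed
ones), and the packaged comparison therefore tests miRNA degrees —
recovering the expected direction (the random network's degrees are
significantly lower). Rank-sum tests use exact enumeration up to a
combined n of 12 (no ties) and the tie- and continuity-corrected normal
approximation otherwise; without the continuity correction the exact and
approximate branches disagree by ~0.07 at the boundary, with it by ~0.01.
Pathway enrichment is upper-tail hypergeometric with Benjamini–Hochberg
q-values, significant at q ≤ 0.05.

## Cross-species comparison

Per-species profiles are arithmetic means of per-sample RPM; the shared
set keeps homologous families detected (RPM > 0) in every species;
species are clustered with average linkage on 1 − Pearson of
log2(RPM + 1) — a standard expression-clustering choice the historical
description leaves open, exposed as configuration. Named-cluster
contrasts (a mouse-restricted miR-467-like cluster, an imprinted-region
cluster, a primate C19MC-like cluster) call presence at ≥ 1 RPM for any
member — a quantitative stand-in for qualitative "almost absent"
language. The cross-species generator plants a 100-family core with the
first two species more correlated than the third and species-restricted
clusters, which the shared-set, clustering and contrast stages recover
exactly.

## Numerical choices and degenerate inputs

* Folding: deterministic traceback (pair-extension branch preferred,
  leftmost k); sequences shorter than 5 nt fold to the empty structure
  at energy 0; non-ACGTU input is an error.
* All-zero clusters yield `NA` divergence; zero-mean rows are excluded
  from `D.I.`; `Pₑ = 1` yields κ = 1 by convention; RPM requires a
  positive mapped total.
* Window extraction clips at chromosome boundaries; minus-strand
  windows are reverse-complemented before folding.
* Thresholds are inclusive wherever the historical material is
  ambiguous (≥ 30 reads; ≤ 10 kb gaps), and each such reading is noted
  at the function it affects.

## Problem sizes

The test-suite and the acceptance script run the full pipeline on the
default three-library 10^5-read study, calibrate the slope-zero null over
100 target-table seeds (40 miRNAs × 600 genes), compare exact and
approximate statistics on enumerable sizes, and verify the folding DP
against exhaustive enumeration on windows of ≤ 16 nt — sizes chosen so
each property is measured at full strength while a complete run stays in
the minutes range on a single CPU.

## Known limitations

* Exact-match mapping and trimming: no error tolerance by default.
* The four consistency statistics implement verbal descriptions, not
  recovered formulas.
* The folding score is a structural proxy, not a nearest-neighbour
  thermodynamic model; its energy threshold is calibrated to the score
  scale, not to experimental ΔG.
* Real-data totals (catalogue sizes, network node/edge counts,
  cross-species intersections) depend on the original annotation and
  external datasets and are out of scope; the package substitutes
  planted-truth recovery for them.
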