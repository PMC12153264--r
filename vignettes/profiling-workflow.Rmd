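---
title: "Phylogenetic profiling and neighborhood co-localization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic profiling and neighborhood co-localization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

profscreen implements a genome-mining workflow for detecting functional
linkage between protein families across a prokaryotic genome collection.
Given per-genome gene coordinates (GFF3), precomputed domain-hit tables
(HMMER tblout/domtblout or a simplified TSV) and genome metadata, it

1. calls each genome positive or negative for every family
   (**phylogenetic profiles**),
2. screens all families for over- or under-representation between
   anchor-positive and anchor-negative genomes (**co-occurrence screen**),
3. and, for genomes carrying both an anchor and a partner family, classifies
   the gene-neighborhood relationship of the closest anchor–partner gene
   pair by intergenic distance and strand orientation
   (**co-localization**).

The motivating use case is the linkage between the protein-only RNase P
(HARP, Pfam PF09745) and an Rnl3-type RNA ligase (PF18330/TIGR01209) in
archaea and bacteria from extreme environments, but every stage is
family-agnostic: the anchor and partner are parameters.

Running scans over real genome databases and inferring trees are out of
scope by design; the pipeline consumes hit tables and accepts a Newick tree
only as a passthrough for visualization.

## Presence calling

A genome is positive for a family if it has **at least one** hit passing
the policy; presence is a genome-level call, so multiple gene copies
collapse. The default policy is `e_value <= 1e-5` with no bit-score floor —
conventional for Pfam-style screens — and both thresholds are explicit,
configurable and recorded in the run log, because presence calls are only
meaningful jointly with their thresholds. Family accessions are compared
case-insensitively with Pfam version suffixes stripped (`PF18330.5` ->
`PF18330`), and alias groups let several models stand for one biological
family (the default pipeline config unions `PF18330` and `TIGR01209` into
one partner column, since either model evidences the same ligase). Genomes
listed in the metadata but lacking qualifying hits become all-zero rows;
they are the anchor-negative background, so dropping them would bias every
downstream table. Hits referencing genomes absent from the metadata are an
error, not a warning, for the same reason.

## The co-occurrence screen

For an anchor family $A$ and candidate family $F$, genomes are
cross-tabulated as

|            | $F^+$ | $F^-$ |
|------------|-------|-------|
| $A^+$      | $a$   | $b$   |
| $A^-$      | $c$   | $d$   |

Conditional on the margins, $a$ is hypergeometric, and the test is the
exact conditional test: one-tailed p-values sum a hypergeometric tail; the
two-sided p-value is the sum of probabilities of all attainable tables
whose probability does not exceed the observed table's. Two-sided
conventions differ across software, so this choice (the "minimum
likelihood" rule, the one used by `stats::fisher.test`) is stated
explicitly. All probabilities are computed in log space via log-factorials
(`lgamma`), so the test remains stable when margins reach the thousands;
ties in the two-sided summation are compared with a relative tolerance of
`1e-7`, and a p-value that underflows is clamped to the smallest positive
double so that it stays in $(0, 1]$. When a margin is zero in both rows or
both columns only one table is attainable and $p = 1$ by convention. The
implementation is verified against brute-force enumeration with
`stats::dhyper` over **every** table with $n \le 60$ (about 635,000
tables), to within $10^{-12}$.

Across the screen, q-values are Benjamini–Hochberg step-up adjusted and a
family is called `over`/`under` when its odds ratio is above/below 1 with
$q \le \alpha$ (default $\alpha = 0.05$). The sample odds ratio $ad/bc$ is
reported as-is — the motivating dataset has $c = 0$, giving an infinite
ratio — alongside a Haldane–Anscombe corrected version (0.5 added to every
cell) that is always finite; ranking uses the corrected value. These
defaults are the package's own: they are standard practice for
presence/absence profiling, chosen because published genome-mining prose
rarely prints its exact machinery, and they are configurable precisely for
that reason.

Phylogenetically aware corrections (e.g. treating related genomes as
non-independent observations) are deliberately not attempted; the screen
treats genomes as exchangeable, which overstates significance for clonal
clades. The stratified summaries (per domain of life) are the provided
mitigation.

Conditional co-occurrence for a chosen anchor/partner pair is summarized as
$P(\text{partner}\mid\text{anchor})$ and
$P(\text{anchor}\mid\text{partner})$, globally and per stratum. Exact
fractions are stored; one-decimal and integer-rounded renderings are also
reported because published counts are typically rounded coarsely — the
summaries keep the exact arithmetic authoritative.

## Co-localization and orientation

Distance is the boundary-to-boundary intergenic gap: order the two genes by
start and take $\max(0, \mathrm{start}_\text{right} -
\mathrm{end}_\text{left} - 1)$. Overlapping or abutting genes have distance
0, which makes "abutting" co-localized by construction. GFF3 coordinates
are 1-based inclusive at the boundary and converted to 0-based half-open in
exactly one helper, which also feeds the BED export. A pair is
**co-localized** when both genes share a contig and the gap is *strictly*
below the threshold (default 5,000 bp, so a 5,000 bp gap does not
qualify). Whether published distances are boundary gaps or start-to-start
offsets is usually unstated; the boundary-gap convention is this package's
commitment and the threshold is configurable. Replicons are treated as
linear by default; an optional circular mode takes the minimum of the
linear and wraparound gaps.

Orientation has three exhaustive, mutually exclusive classes determined
only by positions and strands (hence symmetric in the two genes):

* **divergent** ("bidirectional", head-to-head promoters): opposite
  strands, left gene on the reverse strand;
* **convergent**: opposite strands, left gene forward;
* **tandem** (co-linear): same strand.

Convergent pairs are tracked as their own class even where a study's prose
mentions only the other two, so tallies always sum to the co-localized
count.

Each dual-positive genome contributes exactly **one** pair — the
minimal-gap same-contig combination, ties broken by lower anchor then
partner start — because the downstream fractions count genomes, not gene
pairs. Genomes whose anchor and partner genes share no contig still appear,
with `same_contig = FALSE` and undefined distance, so denominators stay
complete. A gene hit by both families is never paired with itself. The
pairing is verified against a brute-force all-pairs scan.

## The synthetic collection

The generator emulates the statistical structure the analysis assumes, so
that every stage can be tested against a known truth without downloads:

* anchor presence ~ Bernoulli(`p_anchor`), partner presence conditional on
  the anchor state (`p_partner_given_anchor` / `p_partner_given_no_anchor`),
  background families mutually independent of everything;
* dual-positive genomes carry a planted adjacent anchor–partner pair: with
  probability `p_coloc_given_both` the gap is drawn uniformly below the
  5 kb threshold and the orientation from `orientation_mix`; otherwise the
  pair is planted far apart (gap uniform on [5,000, 40,000] bp) or, with
  probability `p_far_second_contig = 0.2`, the partner moves to a second
  contig — exercising the cross-contig code path;
* background genes are laid left-to-right with exponential gaps (mean
  500 bp, capped at 5 kb so placements are boundedly feasible) and lengths
  uniform on [300, 1500] bp; genes never overlap. These placement constants
  are arbitrary but stated; nothing the tests assert depends on them beyond
  feasibility, which is checked against the contig length before any file
  is written.

Defaults are the study conditions used throughout the tests and the
analysis scripts: 500 genomes, anchor prevalence 0.5, partner prevalence
0.9 given the anchor versus 0.05 without it, 200 background families at
prevalence 0.3, co-localization probability 0.8, orientation mix 90%
divergent / 10% tandem (convergent 0 — matching a linkage where divergent
orientation dominates and tandem is the rare minority), and an
archaeal fraction of 573/751. A desk-scale collection cannot reproduce the
rarity of an anchor found in ~750 of a million genomes — prevalences are
scaled up so that both anchor classes are populated at testable sizes; what
carries over is the *conditional* structure (the 0.9 vs 0.05 contrast and
the co-localization rates), which is what the screen and the neighborhood
stage measure.

Each genome's placement draws from a substream seeded deterministically
from the collection seed and the genome index, so emitted files are a pure
function of parameters and seed (tested byte-for-byte). The
`TruthManifest` records every planted state and realized count;
self-consistency tests require that re-ingesting the emitted files through
the parsers reproduces the manifest **exactly**, not statistically.

What the generator does not emulate — and what passing tests therefore do
not show about real data: phylogenetic correlation among genomes (real
presence patterns are clade-structured), multi-copy families, fragmented or
mis-annotated assemblies, contaminated bins, and any sequence-level signal.
`fixture_from_counts()` complements it with fully deterministic fixtures
built from printed per-domain counts, used for worked-example arithmetic.

## Numerical and design notes

* Degenerate inputs: empty GFF3 or comment-only hit files parse to empty
  tables; malformed lines are skipped with per-line warnings; an anchor
  column that is all-positive or all-negative is an error because the
  comparison is undefined; an empty anchor column in the co-occurrence
  summary yields `NA` percentages rather than 0.
* Tie-breaks: nearest-pair ties resolve by (gap, anchor start, partner
  start); orientation for genes with equal starts resolves by treating the
  first argument as left, which can only occur for overlapping genes whose
  gap is 0.
* Whether a published screen unions several models for one family or runs
  them separately is often unknowable from prose; the alias-group mechanism
  makes either choice explicit instead of guessing.
* Stratified comparisons can be run per domain of life by subsetting the
  metadata before matrix construction; the screen itself is
  stratum-agnostic.

## Problem sizes

The test suite and the acceptance script size their simulations for a
single CPU: the exact-test oracle sweep is exhaustive to $n \le 60$; null
calibration uses 50 replicates of 500 genomes with 200 background families;
planted-truth recovery uses 20 replicates of 2,000 genomes (presence level)
and collections of 1,000 genomes (gene level); byte-determinism and
re-ingestion use 10 seeds at 20–25 genomes. These sizes are the package's
chosen desk-scale study conditions; the statistical assertions
(99% binomial intervals, a 0.01-level binomial check of the FDR rate) are
sized to be decisive at them.
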