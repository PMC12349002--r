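---
title: "Reconstructing ancestral karyotypes from gene-order synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral karyotypes from gene-order synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

karyoforge reconstructs the chromosome complement of an ancestral genome
from the conserved gene order of its descendants, paints extant genomes by
their ancestral chromosome of origin, and quantifies how synteny blocks are
preserved, duplicated and distributed. This vignette explains the model
behind each step, the tunable parameters and their defaults, what the
bundled simulator does and does not emulate, and the design choices made
where the methodology left room.

```{r setup, message = FALSE}
library(karyoforge)
library(dplyr)
```

## The coordinate system: gene-rank space

All synteny work happens in *gene-rank space*: within each chromosome,
genes are sorted by start coordinate and indexed `0..n-1`. A homologous
gene pair between two genomes becomes an *anchor* — a point in the
two-dimensional rank space of a chromosome pair, exactly as in a
homologous-gene dot plot. Base-pair coordinates are retained (internally
0-based half-open, whatever the input format) but are used only where
physical extent matters, i.e. for transposable-element composition.

Working in rank space makes the method robust to the enormous intergenic
and repeat-content differences between genomes: a 10 Gb conifer genome and
a 4 Gb gnetophyte genome chain identically if their gene orders agree.
Strand is read and stored but deliberately ignored during chaining;
inversions are detected as blocks of `-` orientation instead.

## Homology input

The package consumes standard 12-column tabular aligner output. Two
filters are applied on read:

* an E-value ceiling (`evalue_max`, default `1e-5`), the conventional
  threshold for proteome-scale all-vs-all searches;
* a per-query hit cap (`top_k`, default 5, boundary ties kept). The cap is
  not part of the published filtering but is standard dot-plot practice:
  without it, large gene families flood the anchor set with off-diagonal
  noise. Keeping ties makes the result independent of input order.

## Block chaining

`chain_anchors()` extracts collinear blocks per chromosome pair by
iterated best-chain dynamic programming. A chain is legal when both rank
coordinates move strictly monotonically (rank_b decreasing for `-`
blocks) and consecutive anchors are separated by at most `max_gap` genes
on either axis; its score is simply its anchor count. The best chain over
both orientations is removed as a block and the search repeats until the
best remaining chain has fewer than `min_pairs` anchors.

Numerical choices:

* **Score = anchor count, no affine gap penalty.** Gap legality is a hard
  constraint; among equal scores the chain with the smaller reference span
  wins, then the smaller starting rank, then orientation `+`. This makes
  the output fully deterministic, which the test suite exploits (an
  exhaustive enumeration oracle must agree with the DP on every random
  instance).
* **Defaults `max_gap = 25`, `min_pairs = 5`** follow the defaults common
  to collinearity tools of this family; both are arguments everywhere.
* **Greedy iterated extraction**, not a global simultaneous optimisation:
  standard, testable, and each anchor ends up in at most one block.
* Self-comparisons keep the trivial identity diagonal through chaining;
  `filter_blocks(self_mode = TRUE)` then removes blocks on the same
  chromosome with ≥ 90% of anchors at `rank_a == rank_b`, so paralogy
  depth statistics never count a genome matching itself.

## Chromosome-pair relations

`classify_homology()` reduces a filtered block set to one relation per
chromosome pair: `whole`, `arm`, or `segmental`. `whole` requires
reciprocal span coverage of at least `theta_whole` *and* mutual top
partnership. `arm` requires the blocks to cover at least `theta_arm` of a
single arm of the partner (given centromere ranks); when no centromere
table is supplied, arm classification is disabled rather than guessed.

`theta_whole` defaults to **0.8**. We read "homologous across the entire
length" strictly: simulation showed that at 0.6 a chromosome that is a
60/40 translocation mix of two ancestral chromosomes passes the reciprocal
test against a pure partner, and transitive seed unification then chains
distinct ancestral chromosomes into one seed. At 0.8 a pure pair still
passes comfortably under realistic gene loss (coverage of intact pairs in
simulation is ≥ 0.95) while mixed products fall through to round 2, where
they are handled at segment level. `theta_arm` stays at 0.6 since an arm
hit is genuinely partial.

## Two-round ancestral reconstruction

`build_ancestral_karyotype()` runs the reconstruction over an ordered list
of builder species:

1. **Round 1 — seeding from whole chromosomes.** Every `whole` relation
   between two builder species joins its two chromosomes into a seed;
   seeds sharing a chromosome unify transitively (union–find). Inversions
   do not disturb this round because relations are coverage-based. A seed
   that would contain two different chromosomes of the same species is a
   hard error: the whole-chromosome evidence is then self-contradictory
   and no automatic resolution is defensible.
2. **Round 2 — segment-level residual assignment.** Seeded chromosomes are
   masked. For every remaining chromosome, the hull of the block spans
   linking it to one proto's members becomes a candidate segment; it is
   accepted when the evidence involves at least `min_species` distinct
   species; the chromosome's own species counts toward the bar, so at the
   default `min_species = 3` evidence spanning three genomes in total
   suffices. A chromosome may
   contribute different segments to different protos, which is exactly
   what translocation and fusion products require. Residual segments
   linked only to each other found a new proto when their connected
   component spans at least `min_species` species. Conflicting overlapping
   claims are reported and left unassigned.
3. **Consolidation.** Two protos merge when their member segments are
   *directly homologous* — blocks connecting a member segment of one to a
   member segment of the other across at least two distinct species pairs
   — and no species carries the two protos as near-whole chromosomes
   apart. Mere adjacency on a rearranged junction chromosome is not merge
   evidence: simulation showed that co-localization support (two protos
   sharing junction chromosomes) merges ancestral chromosomes that were
   only ever joined by a lineage-specific translocation. Merges whose
   transitive closure would join a contradicted pair are refused.
4. **Representative selection.** Within each proto region, candidates
   covering at least 80% of the region's maximal extent compete on
   *continuity* (anchors in the segment divided by its rank span); ties go
   to more anchors, then to the lexicographically first source. The 80%
   floor stops a short, dense fragment from displacing a full-length
   segment — without it a 50-gene fragment with slightly tighter anchor
   packing can collapse a 400-gene proto-chromosome. Proto ids are finally
   assigned by descending gene count (`AGK1` largest), and the ancestral
   gene list is the concatenation of representative segments with
   source-species provenance, so the reconstructed karyotype is a mosaic
   of real gene models from several genomes.

Species roles are explicit configuration; nothing in the algorithm depends
on taxon names.

## Painting

`project_karyotype()` assigns each target gene inside a block's rank span
the block's proto-chromosome; overlaps resolve to the block with more
anchors. A light majority smoothing then absorbs discordant runs shorter
than 3 genes that disagree with the surrounding `smooth_window` genes
(default 30). Genes outside every block stay `NA` — the painting never
extrapolates. Because the ancestral gene set consists of source-species
genes, the same homology tables used for reconstruction drive painting,
including the self pair when a source genome is painted (the
self-projection identity: a genome painted against a karyotype built from
itself is ≥ 99% painted, each chromosome monochromatic — one of the
package's acceptance checks).

## Block statistics

* **Collinearity degree** — gene pairs per block; the summary used to
  compare how well different genomes preserve the ancestral order.
  Undefined (NA, with a warning) when there are no blocks.
* **`anova_oneway()`** — classical equal-variance one-way F test across
  groups of degree values, plus an optional label-permutation p-value as a
  robustness companion. Both per-species degree values and per-block pair
  counts can be fed in, since either grouping is defensible.
* **`arm_randomization_test()`** — under the null, each block lands on arm
  *a* with probability proportional to arm length; the statistic is the
  chi-square form and the Monte-Carlo p-value uses the +1 correction so it
  is never exactly zero (`n_sim` default 10,000, seed mandatory). Arm
  length is measured in genes by default, keeping the null consistent
  with rank-space blocks; a bp-based table can be supplied instead.
  Calibration is verified by simulation: under the null the p-values are
  uniform (KS test) and the empirical type-I error at 0.05 sits in
  [0.03, 0.07].
* **`te_composition()`** — repeat composition inside each block's bp span
  versus the spans of the `flank_genes` (default 30) genes on either side.
  Intervals are merged per class before measuring, so nested annotations
  are never double-counted; flanks truncated at chromosome ends are
  flagged. Enrichment reporting is descriptive (block minus flank per
  class); no significance claim is attached.

## The simulator

`simulate_evolution()` is first-class, tested code, not a fixture: it is
the package's ground truth for end-to-end validation. It builds an
ancestor of `n_protos` chromosomes (default 12, a few hundred genes each),
evolves one descendant per species along a star tree — per branch:
whole-genome duplication, reciprocal translocations, fissions, fusions,
inversions, gene loss, gene gain, in that fixed order so the event log
replays exactly — and emits gene tables, noisy homology tables for every
species pair (plus self and ancestor pairs), class-structured TE
landscapes, the event log, and the per-gene truth painting.

Design notes:

* Evolution happens in gene-rank space; bp coordinates are synthesized
  from per-gene lengths (sampled once at gene creation) and a fixed 3 kb
  intergenic gap. The fixed gap keeps replay free of randomness, so
  "replaying the log reproduces the descendant exactly" is a hard
  invariant, and TE composition still gets realistic physical spans.
* Homology noise: each true pair is dropped with `p_missing` (default
  0.02) and `round(p_spurious * n_true)` random pairs are added with
  plausible (lower) bitscores. Public gene ids are assigned after all
  events in genome order, so nothing about the truth leaks through ids.
* WGD is instantaneous doubling; fractionation is independent per-copy
  loss applied by the same loss machinery afterwards.
* TE landscapes are per-class Poisson processes (defaults: Copia 6,
  Gypsy 10, LINE1 8, Other 4 elements per Mbp, with class-typical
  lengths), with an optional LINE1 intensity multiplier inside designated
  gene windows — the generative mechanism behind a block-versus-flank
  LINE1 contrast.
* The default validation scenario mirrors a clade with stable karyotypes
  plus one duplicated lineage: 5 species, star tree, per branch 5
  inversions, 1 reciprocal translocation, 5% loss, 2% gain, WGD in one
  designated species which is excluded from reconstruction and painted
  afterwards.

What the simulator does **not** emulate: nucleotide sequences and hence
alignment-score realism; divergence-dependent homology detection (noise is
uniform, not branch-length dependent); tandem duplications and gene-family
expansions; segmental duplications; realistic gymnosperm genome sizes
(desk scale is tens of Mbp). Passing the recovery tests therefore shows
the pipeline's logic is sound under the modelled processes, not that every
real-genome complication is handled.

## Validation summary

The acceptance suite (also reproducible via `scripts/acceptance.R`)
checks, among others: chaining equals exhaustive enumeration on 200 random
instances; self-projection identity; recovery of the simulated
12-chromosome ancestor in at least 18 of 20 runs of the default scenario
with mean painting accuracy ≥ 0.95 and accuracy decreasing monotonically
as the per-branch inversion count rises from 5 to 50; a modal 2:1 syntenic
depth for a duplicated descendant against its ancestor, robust to 30%
fractionation; randomization-test calibration; exact agreement of the
degree, ANOVA, arm-count and TE-percentage statistics with hand
computations; and recovery of a 4-fold LINE1 intensity multiplier from the
block-versus-flank contrast within 20%. Problem sizes (12 proto-
chromosomes of 200–500 genes, five species, 20 + 30 replicate runs) were
chosen so the whole suite validates the full pipeline in minutes on a
single core.

## Known limitations

* Round-2 membership is tracked as one contiguous rank hull per
  (chromosome, proto); a proto twice interleaved on the same chromosome
  is summarised by one span.
* When consolidation merges redundant partial protos (the same ancestral
  content seeded twice), each region keeps its own representative, so the
  ancestral gene list can contain partially overlapping content; painting
  is unaffected because both regions carry the same proto id.
* Splice variants must be pre-collapsed to one model per gene; the reader
  does not attempt collapsing.
* Centromere ranks are an input; when absent, arm-level analyses are
  disabled rather than inferred.
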