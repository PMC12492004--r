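---
title: "Synteny blocks, rearrangement indices and K2P distances: methods"
author: "karyotypeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny blocks, rearrangement indices and K2P distances: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotypeR)
```

This vignette documents the models and procedures implemented in
`karyotypeR`, the assumptions behind them, the tunable parameters and
their defaults, what the simulator does and does not emulate, and the
numerical choices a maintainer would want to know about.

## The data model

An `AnchorSet` is one genome's karyotype: chromosome names and lengths
(a `Seqinfo`) plus gene anchors (a `GRanges` with a unique `gene_id`).
A `HomologyMap` binds two `AnchorSet`s with a strictly one-to-one
ortholog pair table; one-to-oneness is enforced at construction, because
every downstream statistic assumes it. Duplicated pairings in input
tables — common in real ortholog calls — are resolved by a
*best-score* policy (highest score wins; ties broken by lexicographic
partner id), with a *strict* mode that refuses duplicates outright. The
number of dropped pairs is always reported.

Anchors enter and leave the package in the BED convention (0-based
half-open); internally they are stored in the GRanges convention
(1-based closed), which is what every Bioconductor operation expects.
The two conventions are interconverted only at file boundaries, and the
readers and writers round-trip exactly. GFF input is deliberately out of
scope; users convert to BED first.

## Rank-space chaining

Synteny is computed in *rank space*: within each chromosome, the paired
anchors are numbered $0..k-1$ by the deterministic key (interval
midpoint, then start, then gene id). Working with gene adjacency rather
than base pairs makes the blocks robust to unequal intergenic distances
and assembly gaps; base-pair spans are derived from the member anchors
afterwards. Unpaired genes occupy no rank, so a sprinkling of
genome-specific genes does not break collinearity.

`chainBlocks()` scans, for each (reference chromosome, query chromosome)
pair, the pair's anchors in reference order and greedily extends maximal
runs in which query ranks advance monotonically with a constant sign and
every step's rank jump — on *both* genomes — is at most `maxGap`.
Bounding both sides makes `maxGap` behave like the gap parameter of
standard collinearity scanners: a run tolerates up to `maxGap − 1`
interleaved anchors that map elsewhere, on either genome. Greedy
left-to-right maximal extension is used because step admissibility is
local (every contiguous sub-run of a valid run is valid), which makes
the greedy partition a minimum-segment partition; a corollary, covered
by a property test, is that increasing `maxGap` never increases the
number of runs.

Defaults are `maxGap = 2` and `minBlockAnchors = 5`, typical
collinearity-scanner settings; both are surfaced in the CLI and echoed
into output headers. Runs shorter than `minBlockAnchors` are reported in
a residue table rather than silently dropped. Orientation of a block is
the sign of its query-rank progression; strand annotations do not enter
the definition, so strand-agnostic ortholog tables work unchanged.

## Rearrangement calls

For each reference chromosome, the *majority partner* is the query
chromosome holding the plurality of its paired anchors (ties broken by
lexicographically smallest name, for determinism). Blocks on the
majority partner are *collinear* or *inversion* according to whether
their orientation matches the anchor-count-weighted dominant orientation
of that chromosome pair (ties default to `+`); blocks on any other query
chromosome are *translocation_insertion*. This majority logic means an
inversion is always called relative to the bulk of its own chromosome
pair, not to a global convention, so a whole-chromosome flip (an
assembly orientation artifact, not a biological event) produces no
inversion calls.

*Macro-fragment* inversions are inversion calls whose reference span
reaches `minSpanBp`, default 1 Mb. The threshold is a reporting
convention, not a biological constant, and is configurable.
`genesInCalls()` intersects call spans with gene annotation (half-open
overlap semantics) to produce the per-call gene lists that downstream
enrichment tools consume.

Fusions and fissions are not block-level events; they are detected by
`chromosomeCorrespondence()` from anchor-sharing fractions: a reference
chromosome whose anchors split across ≥ 2 query chromosomes, each
holding at least `minPartnerFraction` (default 0.2, valid range
(0, 0.5]), is fission-like; a query chromosome fed by ≥ 2 reference
chromosomes at the same threshold is fusion-like.

## The rearrangement index

The index treats reference-genome anchor adjacencies as the unit of
comparison. An adjacency between consecutive ranked anchors is
*conserved* iff both genes sit on the same query chromosome at adjacent
query ranks (unsigned, so reversed neighbours still count as adjacent);
otherwise it is a breakpoint, *intra*-chromosomal if the genes still
share a query chromosome and *inter*-chromosomal if not. With $n$
adjacencies, $C_i = b_\mathrm{intra}/n$, $S_i = b_\mathrm{inter}/n$,
$R_i = C_i + S_i$. By construction $0 \le R_i \le 1$, $R_i = 0$ exactly
for conserved gene order, and a uniformly shuffled chromosome drives
$R_i$ towards 1. A planted interior inversion adds exactly 2 intra
breakpoints; a translocation adds 2 inter (the excision flanks) plus 1
intra (the insertion gap) — so inversions move only $C_i$ while
translocations move both components, matching the interpretation of
$C_i$ versus $S_i$ as intra- versus inter-chromosomal rearrangement
load. The definition is printed in every index file header. The index is
directional (reference → query); the CLI computes both directions by
default, and on the simulator's ground truth both directions agree.

The index is *unweighted*: every adjacency counts equally, regardless of
the base-pair distance it spans. A length-weighted variant would rank
large and small events differently; the unweighted form was chosen
because it is parameter-free and exactly oracle-checkable by adjacency
enumeration.

## Kimura 2-parameter distances

Transitions are A↔G and C↔T; every other mismatch is a transversion.
Sites where either sequence carries anything outside A/C/G/T are
excluded *per pair* (pairwise deletion, the common practice for
marker-gene matrices — complete deletion would let one gappy sequence
shrink every comparison), so each matrix entry has its own
comparable-site count. The distance is
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$. When $1-2P-Q \le 0$ or
$1-2Q \le 0$ the correction is undefined ("saturated"): a single pair
raises a classed error, while the matrix routine reports the entry as
`NA` with a warning so one saturated pair cannot sink a whole matrix.
Distances are reported to 6 decimals; percentages appear only in
display layers.

`delimitSpecies()` summarises a matrix by species labels and flags pairs
whose *mean* between-species distance exceeds the threshold (default
0.02, the conventional mammalian cox1 cutoff); minimum and maximum are
reported alongside so a user can apply stricter rules.

## The simulator and what passing tests mean

`simConfig()` defaults describe the study scale: 22 chromosomes (the
distinct-chromosome count of a 2n = 44 balaenopterid karyotype), 45
anchors per chromosome — roughly the ~900 ortholog anchors of a real
whale chromosome scaled down 20-fold so that simulations stay fast — and
100 Mb chromosomes, giving ~2.2 Mb anchor spacing, so any planted
inversion of ≥ 5 anchors is macro at the 1 Mb threshold. Operations
(inversion, translocation with optional inversion-on-move, fusion,
fission) are drawn in seeded random order and applied sequentially;
segment sizes are uniform on `segmentRange` (default 5–10 anchors). The
ground-truth log replays bit-identically, and gene content is invariant
under all operations.

Two modes matter for interpretation. In the default mode later
operations can compound earlier ones, which is realistic but makes exact
bookkeeping ambiguous. In `nonOverlapping` mode every operation claims
its chromosome(s) exclusively and stays clear of chromosome ends, so
each planted operation leaves its textbook breakpoint signature: that is
the mode under which the suite asserts *exact* recovery of operation
counts and breakpoint increments (200 seeded runs with 1–5 inversions
and 0–2 translocations each). Passing those tests shows the chaining,
classification and index machinery is correct on clean ground truth; it
does not show robustness to compounded rearrangements, missing
orthologs, assembly errors or fragmented scaffolds, which real data
contain and the simulator deliberately does not model (no sequence-level
breakpoint features, no anchor noise, no missing genes).

K2P sequence pairs are simulated from the exact closed-form transition
probabilities of the K2P rate matrix (each descendant evolved
independently for $d/2$), not by event sampling — cheaper, and exactly
matched to the estimator under test. The estimator is additionally
cross-checked against an independent reference implementation
(`ape::dist.dna`, model `"K80"`) in the test suite.

## Numerical and design choices

* **Tie-breaks.** Anchor ordering key (midpoint, start, gene id);
  majority partner ties by name; dominant orientation ties to `+`. All
  deterministic, so outputs are byte-stable across runs and platforms.
* **Degenerate inputs.** An index over zero adjacencies (no chromosome
  with ≥ 2 paired anchors) is an error, not 0 — the quantity is
  undefined. Empty block or call sets write header-only files that read
  back as empty tables.
* **Coordinates.** 1-based closed inside (GRanges), 0-based half-open in
  files; `span_bp` equals the half-open span length in both conventions.
* **Seeds.** Every stochastic routine takes an explicit seed
  (`simConfig(seed=)`, `simulateK2pPair(seed=)`) and is a pure function
  of it; layout, operation draw and sequence evolution share no hidden
  state.
* **Allosomes and scaffolds.** Sex chromosomes are ordinary chromosomes
  by default and can be excluded with `dropChromosomes()`; a chromosome
  length floor in `readChromTable(minLengthBp=)` (off by default)
  discards unplaced scaffolds.
* **Problem sizes.** The validation suite uses exhaustive permutations
  to $n = 8$ anchors for the breakpoint oracle, 200 simulated
  22 × 45-anchor genomes for recovery, and 100 replicates of 10 kb
  alignments at $d^* = 0.03$ for K2P recovery — sizes chosen so the full
  suite completes in a few minutes while keeping the exhaustive checks
  genuinely exhaustive.

## Known limitations

* The chaining is greedy single-path, not gap-penalised dynamic
  programming; many-to-many homology and base-pair-scored chaining are
  out of scope.
* Rearrangement distance metrics (DCJ, HP) and ancestral karyotype
  reconstruction are not implemented; $R_i$ is a descriptive fraction,
  not an evolutionary distance.
* No statistical test is attached to comparisons of $C_i$/$S_i$ between
  genome pairs; the index ranks, it does not test.
* `delimitSpecies()` applies a fixed distance threshold; it is a
  screening device, not a substitute for coalescent-based delimitation.
* Sequences must be pre-aligned; only the K2P model is offered (no
  JC69/TN93, no bootstrap).
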