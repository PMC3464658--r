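---
title: "Detecting long tandem duplications from DNA alone"
author: "tandemscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long tandem duplications from DNA alone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscan)
```

## The problem

Tandem duplication copies a stretch of a chromosome next to itself. Over
time the copies diverge — substitutions, indels, occasional inversions —
until no single local alignment covers a whole copy pair and only scattered
fragments of similarity remain. Annotation-driven approaches find tandem
*gene* arrays by clustering paralogous proteins, but in doing so they
censor everything that is not an annotated coding gene: pseudogenes, RNA
gene clusters, gene relics, unannotated copies. `tandemscan` works directly
on the DNA: it reconstructs long, partially conserved tandem arrays from a
genome self-comparison only, and optionally scores its calls against an
annotation afterwards.

Throughout, a sequence `S` is compared against itself in the classical
dotplot picture. A local self-alignment, or **anchor** `a`, pairs two
intervals `a0` and `a1` of `S` (by convention `a0` starts first) with an
alignment score and a sign (`+` same strand, `-` inverted). An anchor can
only witness a tandem duplication if its two intervals do not overlap and
lie at most `T` bases apart. Three structural parameters govern everything:

| parameter | meaning | default |
|---|---|---|
| `ell` | minimum duplication unit length | 500 bp |
| `T` | maximum distance between two copies of a duplication | 150 kb |
| `L` | maximum gap between chained anchors; also the margin added around an array | 40 kb |

The defaults are sized for compact plant/invertebrate-style genomes where
tandem gene arrays span tens of kilobases; all are configurable
(`tandem_config()`).

## Stage 1 — anchors

`find_anchors()` is a seeded gapped X-drop local self-aligner. All unmasked
exact 12-mers of the sequence (and of its reverse complement) are indexed;
every non-trivial seed pair — the main dotplot diagonal and any
self-overlapping extension are excluded constructively — is extended in
both directions under the scoring scheme *match +1, mismatch −3, gap open
−5, gap extend −2*, stopping when the running score drops `xdrop = 20`
below the running maximum. Alignments scoring at least 30 whose interval
pair satisfies the tandem conditions (disjoint copies at most `T` apart)
become anchors. Low-complexity sequence is soft-masked first with a DUST
scorer (window 64, threshold 20, the published defaults; masked bases are
skipped only for seeding, so coordinates and reported sequences are
unaffected). Users with their own aligner can import anchors through
`read_anchor_table()` instead.

Seed length, X-drop and the reporting threshold are implementation choices
(no published values exist for the original aligner); they are deliberately
permissive because downstream chaining tolerates noise far better than it
recovers missed anchors. `dedupe_anchors()` then removes near-duplicate
anchors — pairs overlapping on *both* projections by more than half of the
smaller interval keep only the better-scoring anchor — which both trims
redundant seeds of the same alignment and guarantees termination of the
chaining stage (see below).

## Stage 2 — chains by minimum-cost flow

Anchors are chained under the colinearity order: `b` can follow `a` when
both share a sign and their interval midpoints advance on the first axis,
and advance (sign `+`) or recede (sign `-`) on the second. Midpoints are
used for ordering because alignment boundaries are fuzzy; gaps, however,
are measured between full intervals. The distance between chainable
anchors is `2·max(D0, D1) − min(D0, D1)` over the two per-axis gaps, which
favours pairs sitting on the same dotplot diagonal. Edges longer than `L`,
or whose merged projections would overlap, are removed, and only the `k =
15` cheapest edges leave any vertex.

Costs reward both alignment quality and repetitiveness: a vertex costs
`−m_a · score`, where `m_a` is the mean anchor coverage of the anchor's two
intervals, so anchors lying in heavily duplicated regions are preferred.
Edge distances are rescaled so that their mean equals the absolute mean
vertex cost, making a typical extension cost-neutral and a diagonal
continuation profitable.

A set of chains is only meaningful if (i) each chain's two projections are
disjoint and at most `T` apart — otherwise it is not a candidate tandem
duplication — and (ii) no two chains claim the same duplication, i.e. no
pair overlaps substantially on both axes. Condition (ii) is global, so
greedy repeated chain extraction cannot enforce it. Instead the anchor DAG
becomes a unit-capacity transportation network (each anchor split into an
in/out vertex pair carrying the vertex cost, all vertices tied to a source
and sink), and flow is grown one unit at a time along the cheapest
residual path — the successive-shortest-path scheme for minimum-cost flow.
A flow of value `f` decomposes into exactly `f` vertex-disjoint chains of
minimum total cost among all such sets. After each augmentation the chain
set is tested; the first flow value passing both conditions is returned.

Numerical notes, all deliberate choices:

* Vertex costs are negative, so shortest paths need node potentials:
  initial potentials come from a topological relaxation of the acyclic
  base network, after which reduced costs stay non-negative and plain
  Dijkstra applies. Tiny negative reduced costs from floating-point
  rounding are clamped to zero.
* Ties between equal-cost paths are broken deterministically by a fixed
  arc ordering (sorted by head vertex), making the whole pipeline
  reproducible byte for byte. Full lexicographic tie-breaking inside the
  search would buy nothing beyond that determinism.
* The per-chain test (i) is strict; the pairwise test (ii) flags a pair
  only when both projections overlap by more than the dedup fraction
  (0.5 of the smaller interval). Using a stricter pairwise test would be
  unsound: after dedup two anchors may legitimately overlap up to that
  fraction, and the loop's terminal state — maximum flow, every chain a
  single anchor — must be consistent for termination to be guaranteed.
* A run frequently stops at a small flow value, leaving many anchors in
  no chain. These *residual anchors* are not discarded; they are
  first-class vertices of the next stage.

## Stage 3 — tandem arrays and their reference units

Chains and residual anchors that overlap on either axis by at least half
of the smaller interval (configurable `min_overlap`) are connected in an
undirected overlap graph; each connected component delineates one
**tandem array**, the smallest interval containing all member projections,
enlarged by `L` on each side (clamped to the sequence).

Each array then gets a **reference duplication unit**. The candidate is
the longest projection of the array's minimum-cost chain (ties: longer,
then smaller id; anchor-only components use their longest anchor
interval). Because a single chain may span several copies, the candidate
is aligned against itself: while at least half of it is covered by
off-diagonal self-alignments, the weakest self-alignment is located, the
candidate extremity nearest to it is determined, and the candidate is cut
at that alignment's inner boundary — removing at least one copy of the
internal repeat per iteration, so the loop terminates. If trimming would
push the candidate below `ell`, the untrimmed candidate is kept and
flagged `unresolved_unit`. Arrays whose candidate is shorter than `ell`
are dropped.

## Stage 4 — reconstruction of the individual units

The reference unit is re-searched against its array region. The default
mode emulates a translated (TBLASTX-style) search entirely in-process: the
unit's three forward frames against all six frames of the region, seeded
BLOSUM62 local alignment (word size 3, gap open −11/extend −1, X-drop),
hits mapped back to nucleotide coordinates. Query reverse frames are
redundant — only the relative orientation matters — so they are skipped. A
`nucleotide` mode reuses the DNA aligner, and an `external` mode shells
out to a `tblastx` binary when fidelity to the original tool chain
matters.

The hits form a second chaining problem with the unit on one axis. The
same graph construction applies (per-axis coverage profiles replace the
single-axis profile, and the span-disjointness requirement is dropped —
the axes are different coordinate systems). Extraction, however, is
greedy successive shortest-path *extraction*: repeatedly take the most
negative-cost path through the DAG, remove its vertices, and stop when no
negative path remains. Two facts make this the right tool here, where the
flow iteration is not: a chain is monotone on the unit axis, so one
extraction collects the hit fragments of exactly one traversal of the
unit (one copy); and because source/sink arcs are free while edges cost,
a minimum-cost *maximum* flow provably decomposes into single-hit chains,
destroying exactly the fragment-grouping one needs.

A chain becomes a **tandem unit** when the union of its hits covers at
least `min_unit_fraction = 0.5` of the unit and its region-axis span is at
least `ell`. Region overlaps between units (possible when two chains
split the unit axis) are resolved by trimming the lower-scoring unit,
dropping it if it falls below `ell`. Finally each unit is enlarged by up
to 25% of its own length per side — without leaving the array or touching
a neighbour; two neighbours that both want the same gap split it equally.

## Evaluation layer

Where an annotation exists, a reference truth set is built exactly as the
annotation-driven studies build theirs: genes longer than 500 bp whose
proteins hit each other with e-value ≤ 1e−5, coverage ≥ 70% of both, and
distance < `T` are linked; connected components of ≥ 2 genes are the
reference tandem gene arrays (TGAs), their members the tandem gene units
(TGUs). A TGU is *detected* when a single predicted unit covers ≥ 70% of
it; a TGA when a predicted array covers > 70% (strictly) of its span and
at least one member TGU is detected. The same 70% rule drives the
per-annotation-class report and the orphan statistics (a unit is an
orphan when it neither covers ≥ 70% of, nor is covered ≥ 70% by, any
feature; an array is an orphan when it has no non-orphan unit — an
unitless array is vacuously orphan). BLASTP itself is out of scope: the
hit table is a plain TSV, so the layer is fully testable on synthetic
proteins.

## The simulator

`simulate_genome()` is the package's study-condition generator: i.i.d.
background at GC 0.36 (plant-like), arrays of a random unit replicated
with independent per-copy substitutions, geometric indels (p = 0.7,
capped at 50 bp so truth coordinates stay exact), and optional
reverse-complement inversion, with short spacers between copies. The
defaults — 300 kb, 8 arrays, units of 600–3000 bp, 2–6 copies, 3%
substitutions, 0.5% indels — are the calibration conditions used by the
test suite and the acceptance script; inversions default off and are
exercised explicitly in tests. `simulate_annotation()` adds one "gene"
per planted copy, background decoys, and a hit table linking co-array
copies, which closes the loop for the evaluation layer.

What the simulator does *not* emulate matters for interpreting green
tests: real genomes carry transposon families, satellites and segmental
duplications that produce anchor clouds far denser than i.i.d. background,
and real tandem arrays show correlated (not independent) divergence
between copies. Passing the recovery properties here demonstrates the
machinery — chaining, delineation, unit extraction, reconstruction — under
controlled divergence; it does not by itself predict genome-wide
precision on repeat-rich chromosomes, where masking quality and the
dedup/overlap thresholds dominate.

## Problem sizes and degenerate inputs

The test suite runs the full pipeline on simulated genomes of 100–500 kb
with up to ~8 arrays each — sizes at which every oracle (brute-force path
enumeration, per-base recounts, pairwise alignment cross-checks) is exact
and fast. Empty anchor sets, empty chain sets, arrays without units
(`unit_only`), unresolvable units and empty genomes all have defined
behaviour and tests. Degenerate edge rescaling (no edges, or zero mean
distance) falls back to scale 1 with a message.

## Known limitations

* The flow stage is quadratic-ish in anchors per sequence in this
  implementation; genome-scale chromosomes with hundreds of thousands of
  anchors would want the compiled-path version of the same algorithm.
* The stopping rule can leave a well-separated duplication unchained at
  small flow values (its anchors still reach the array stage as residual
  anchors, so arrays and units are unaffected; only chain statistics
  shift).
* Unit boundaries inherit alignment-boundary fuzziness; the ±25%
  enlargement is a heuristic sized to gene-scale units.
* dS-based age stratification of detected pairs is intentionally out of
  scope; the evaluation accepts a precomputed dS column if present.
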