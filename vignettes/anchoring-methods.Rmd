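---
title: "Anchoring a scaffold assembly onto a reference with conserved elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring a scaffold assembly onto a reference with conserved elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Whole-genome alignment of two animal-sized genomes is expensive because a
base-level aligner must explore an enormous space of local alignments.
When the goal is only to *place* the scaffolds of a draft assembly on the
chromosomes of a related reference — assign each scaffold to a
chromosome, order the scaffolds along it, and orient them — most of that
work is unnecessary.  Animal genomes carry a large complement of highly
conserved elements (HCE): short stretches (tens of bases to a few
kilobases) under strong purifying selection that diverge far more slowly
than the genomic background.  Within a mammalian or avian order these
elements are nearly identical between species, and they are dense enough
(roughly 5–20% of the genome, depending on clade and phylogenetic
distance) to serve as a scaffold-resolution map.

scafanchor implements this idea as a five-stage pipeline:

1. **Preprocessing.**  Genomes are read from FASTA (`read_fasta()`),
   uppercased, ambiguity codes collapsed to N, and sequence sizes
   tabulated (`compute_sizes()`).
2. **Databank construction** (`build_databank()`).  The input HCE set is
   aligned to the reference and stringently filtered: an element enters
   the *databank* only if it aligns with **100% identity** (zero
   mismatches within aligned blocks — small gaps may lengthen the
   placement slightly) over **at least 99% of its length**, at **exactly
   one** reference position.  Elements placing at two or more positions
   are discarded: a landmark that is not unique cannot anchor anything.
3. **Target alignment** (`map_databank()`).  Databank elements are
   aligned to the scaffold assembly at a relaxed identity threshold
   (default 90%), because target and reference are different species.
4. **Anchor filtering and transfer** (`filter_anchors()`,
   `transfer_to_reference()`).  Alignments covering less than `min_ali`
   of the element (default 95%) are dropped, elements still aligning to
   multiple target positions are dropped, and each survivor — now an
   *anchor* with exactly one placement on each genome — is re-expressed
   as a gapless scaffold-to-chromosome alignment block by composing its
   two placements through the element.
5. **Chaining, netting, reporting** (`chain_blocks()`, `net_chains()`,
   `annotate_syntenic()`, `scaffold_report()`).  Anchor blocks that are
   co-linear on both genomes are chained with sparse dynamic programming
   and gap penalties; chains are assembled greedily, best first, into a
   per-chromosome *net* in which high-scoring chains occupy the top level
   and lower-scoring chains fill their gaps.  The net yields the
   per-scaffold report: assigned chromosome, span, orientation,
   supporting anchor count, and coverage.

The per-scaffold report is the tool's product.  It is not a base-level
alignment and does not try to be one; it is the skeleton such an
alignment would hang on.

## The aligner

Placing short, highly conserved queries calls for a seed-and-extend
local aligner in the BLAT mold, and the package implements one in C++:

* **Seeding.**  The genome is indexed by its N-free k-mers (default
  k = 11) sampled every `step` = 5 bases.  Query k-mers (every offset,
  both strands) are looked up and hits are clustered by diagonal: hits
  whose diagonals differ by at most `band_width` (default 32) belong to
  one candidate locus.
* **Masking.**  With `occ_threshold` set, k-mers whose genome-wide count
  exceeds the threshold are removed from the index entirely — the
  classical remedy for repeat-driven seed explosions, exposed on the
  command line as `--occ`.
* **Extension.**  Each candidate locus is extended by a banded local
  alignment with affine gaps (match +1, mismatch −1, gap open −3, gap
  extend −1) over the cluster's diagonals ± `band_width`; the traceback
  yields the PSL block structure.  N bases score zero and are tallied in
  `nCount`, never as matches or mismatches.  A locus whose gapless
  prescreen already attains the perfect full-length score is emitted
  directly — no gapped alignment can beat it.  In **fast mode**
  (`fast_mode = TRUE`, the `-fastMap` analog) extension is gapless only
  and queries are limited to 5 kb; longer elements must be split first
  (`split_long_hce()`), which the pipeline does automatically.
* **Candidate screening.**  On large genomes a query accumulates
  hundreds of single-seed chance clusters.  When a query has more than
  64 candidate loci, loci supported by a single seed are extended only
  if a cheap gapless extension of that seed scores at least k + 5;
  multi-seed loci are always extended.  On small genomes (and thus in
  every oracle comparison in the test suite) every locus is extended.
  Alignments spanning fewer than 2k bases are below the seed resolution
  and are not reported.
* **Identity.**  Reported as `matches / (matches + misMatches)`,
  i.e. gaps are not charged; a gap-penalized variant (in the spirit of
  BLAT's milliBad) is available via `psl_identity(gap_penalized =
  TRUE)`.  The blocks-only definition is the default because the
  databank filter expresses its "100% identity" criterion over aligned
  blocks while tolerating small gaps.

One locus yields at most one alignment; ties are broken toward the
leftmost target start and then the forward strand, and overlapping
candidates keep only the best-scoring record.  Output order is
canonicalized by `(qName, tName, tStart)` so results never depend on how
queries were batched.

## Chain scores and gap costs

A chain's score is `sum(block length) × per_base_score` minus a cost for
every inter-block gap.  The cost is piecewise-linear in `max(dt, dq)`
(the larger of the two gap sides) with a flat surcharge of 400 when both
sides gap at once.  Two presets are provided, following the familiar
`-linearGap` naming:

| preset  | breakpoints (bases) | slopes (points/base) |
|---------|--------------------|----------------------|
| loose   | 0, 100, 1000, 10000 | 30, 3, 1, 0.3       |
| medium  | 0, 100, 1000, 10000 | 90, 9, 3, 0.9       |

with `per_base_score = 100`, `max_gap = 10^6`, and a minimum chain score
of 3000 (the conventional chain-construction threshold — about 30
aligned bases).  "Loose" joins anchors across larger gaps and is the
default for anchor chaining, where blocks are sparse by construction;
"medium" is the steeper setting typical of base-level chains.  The
preset *names* are standard; the numeric tables are this package's
documented configuration, chosen to reproduce the qualitative behaviour
(loose bridges what medium will not), and both are overridable
(`linear_gap_model()`).

Within a chain, successive blocks must strictly increase in reference
and in orientation-adjusted scaffold coordinates.  Blocks may overlap
slightly (anchors can, rarely, share sequence); the overlap is trimmed
at its midpoint, a rule chosen because it is symmetric and
order-independent.  The stored chain score always re-scores the emitted
(post-trim) geometry, so `rescore_chains()` reproduces it exactly.

Netting is greedy by descending score.  A chain contributes the pieces
of its reference span that fall inside currently unfilled gaps of at
least `min_space` = 25 bases, snapped to its aligned bases; its own
internal gaps of at least `min_space` become open gaps that later chains
may fill.  25 bases is deliberately permissive — small enough to admit
any fill that could matter at scaffold resolution.  Chains compete
globally per chromosome, across scaffolds, because the net is a
reference-frame structure.

## The synthetic genome pair

Real HCE databanks are derived from multi-species whole-genome
alignments; none can be shipped or downloaded here.  Instead the package
carries a simulator (`simulate_genome_pair()`) that reproduces the
*statistical* structure the method exploits, with full ground truth:

* background sequence is i.i.d. uniform A/C/G/T;
* elements (default 2000, log-normal lengths with median 250 bases,
  clamped to [40, 2000]) are planted non-overlapping, at least 500 bases
  apart; a small fraction is duplicated (2%, to exercise the uniqueness
  filters) or built from a scattered repeat motif (0.5%, to exercise
  seed masking);
* the target is a copy of the reference mutated at 8% substitution
  divergence outside elements and 1% inside (the contrast that makes
  elements anchorable while background is not), with indels at
  5 × 10⁻⁴/base (10⁻² of that inside elements; geometric lengths, mean 2,
  max 20), five inversions and two translocations of 50–500 kb and
  50–300 kb, and finally random fragmentation into scaffolds, resampled
  until the N50 is within 20% of the 150 kb target;
* a signed per-base origin map is carried through every edit, so the
  ground truth knows each scaffold's true chromosome, span and
  orientation, and each element's target coordinates.

These defaults describe a within-order mammalian comparison at desk
scale: two 5 Mb chromosomes stand in for a genome, and the 8%/1%
divergence contrast mirrors the background-versus-conserved gap of such
pairs.  The divergent-pair check raises element divergence to 12% (and
background to 25%, maintaining the contrast), the regime in which the
documented relaxation — `min_identity` and `min_ali` both to 0.80 — is
the appropriate setting, and verifies that relaxing strictly increases
anchors and mapped length.

What the simulator does **not** model: repeat landscapes and
segmental duplications beyond the toy motif, GC isochores, gene
structure, assembly errors, and polyploidy.  Passing the end-to-end
checks therefore demonstrates that the pipeline's logic is correct under
the model's assumptions — not that any particular real genome pair will
anchor equally well.  On real data, repeat content and assembly quality
dominate, exactly as they do for the tools this package emulates.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally (PSL/BED
  convention); 1-based arithmetic appears only inside IRanges calls.
* For reversed-strand records, per-block query starts are on the
  reversed query and top-level `qStart`/`qEnd` on the forward query
  (PSL convention); chain and net query coordinates are on the stated
  strand (chain-format convention).
* Uniqueness is counted over alignments that *pass* the identity and
  coverage filters: an element with one perfect hit and one 91% hit is
  unique — sub-threshold hits are noise by the filters' own criteria.
  `strict_unique = TRUE` switches to counting every reported hit.
* When an anchor's two placements have unequal spans (a gapped element
  alignment), the transferred block takes the shorter span,
  start-anchored after orientation: sub-anchor base correspondence is
  unknowable without re-alignment, and chaining needs only approximate
  geometry.
* An all-N alignment has identity 1 by convention (empty denominator)
  and its N columns count toward coverage via `nCount`.
* Degenerate inputs error early and by name: empty genomes, duplicate
  sequence ids, non-IUPAC characters, queries shorter than 2k, fast-mode
  queries over 5 kb, alignment records referencing unknown elements.
* Everything downstream of the RNG is deterministic given the seed, and
  worker partitioning cannot affect output order.

## Problem sizes

The test suite validates the pipeline end to end on a pair of 5 Mb
chromosomes with 2000 elements (the simulator's defaults, about two
minutes on one CPU), the chaining DP against brute-force enumeration on
500 instances of up to 10 blocks, the netting greedy against a per-base
reference implementation on 200 random chain sets, and the aligner
against full Smith–Waterman (via Biostrings) on genomes up to 50 kb.
Those sizes were chosen so each oracle is exhaustive at its scale; the
pipeline itself has no such limits and is bounded in practice by the
target-alignment stage, which is linear in the number of databank
elements.

## Known limitations

* The aligner is a functional stand-in for BLAT, not a re-implementation:
  scores, identity bookkeeping and edge behaviour differ in detail, and
  translated or spliced alignment is out of scope.
* Chains and nets are built from anchor geometry only; the gap-cost
  tables are configuration, not fitted values, and no base-level
  alignment happens inside gaps.
* A scaffold whose true placement splits across chromosomes is reported
  with `split_flag = TRUE`, but the report keeps one row per
  (scaffold, chromosome) — reconciling split assignments is left to the
  caller (`find_inconsistencies()` classifies disagreements between two
  mappings).
* Highly repetitive or polyploid genomes violate the uniqueness
  assumption at the heart of the method; expect few anchors there.
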