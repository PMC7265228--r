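---
title: "Models and methods: D-gene cluster architecture, repeats and fusion origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: D-gene cluster architecture, repeats and fusion origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ighdarch)
```

`ighdarch` analyzes duplicated immunoglobulin heavy-chain diversity
(DH) gene clusters: blocks of RSS-flanked gene segments that arose by
segmental duplication and then diverged by point mutation, deletion,
transposition and tandem-repeat expansion. Its motivating application
is the origin of ultralong DH genes — a single bovine DH segment
encodes 49 codons, several times the usual length, and the package
implements the comparative evidence by which such a gene can be
explained as a fusion of the 5' part of one DH with the 3' part of a
neighboring DH, followed by repeat expansion. This vignette documents
the models, the parameters that matter, the synthetic-data generator,
and the numerical choices, in that order. It states no empirical result
that the test suite and the acceptance script do not themselves
compute.

## 1. Coordinates and sequence model

All coordinates are 0-based half-open on the top strand, everywhere
inside the package; BED is written unchanged and GFF3 is converted to
1-based inclusive only at the file boundary. Residues are normalized on
input to `{A,C,G,T,N}` (uppercase, `U→T`, anything else `→N` with a
warning). IUPAC ambiguity codes other than `N` are demoted to `N`
rather than expanded: every statistic in the package is an exact-match
count, and partial-match semantics would silently change identities.
`N` never counts as a match anywhere.

## 2. The RSS model

A D-gene RSS is heptamer + 12-bp spacer + nonamer. On the top strand
the 5' RSS runs nonamer–spacer–heptamer (heptamer against the coding
region) and the 3' RSS runs heptamer–spacer–nonamer; the scanner
(`scan_rss()`) slides a 28-nt footprint and accepts positions whose
heptamer and nonamer are each within a Hamming-distance maximum of the
consensus. The spacer is length-constrained only.

Defaults, with rationale:

| parameter | default | why |
|---|---|---|
| 3' heptamer / nonamer consensus | `CACAGTG` / `ACAAAAACC` | canonical heptamer; nonamer is the majority column of the packaged bovine table |
| 5' heptamer / nonamer consensus | `CACGGTG` / `GGTTTCTGA` | column-wise majority of the packaged table (bovine D-gene 5' RSSs diverge strongly from the canonical form) |
| `max_heptamer_mm`, `max_nonamer_mm` | 3, 3 | the tightest maxima that admit every site in the packaged table — the family-5 5' heptamer `tgtggtg` sits exactly 3 mismatches from the majority consensus |
| strand | top only | D-gene RSSs at this locus are modeled and tabulated on the top strand |

Only the top strand is scanned; all 17 packaged bovine RSS rows are
top-strand. Overlapping hits are all reported; the gene caller resolves
conflicts. The packaged table itself is available as
`ighd_rss_fixture()` / `ighd_rss_sites()` and is the in-package ground
truth for consensus construction and for the RSS-agreement evidence in
fusion scoring.

## 3. Alignment and the single identity definition

All identities in the package come from one affine-gap aligner
(`align()`, Gotoh dynamic programming in C++) and one definition:

> `identity_pct = 100 · matches / columns`, a column matching iff both
> characters are equal and neither is a gap or `N`; gap columns count
> in the denominator; in semiglobal mode, terminal overhang columns are
> not emitted and so never enter the denominator.

Scores default to `match +5, mismatch −4, gap open −16, gap extend −4`
— the EMBOSS Matcher DNA parameterization — with a gap of length *k*
costing `open + (k−1)·extend`. The gap penalties are deliberately this
strong: with weak extension penalties (we measured `−12/−2`), a local
alignment between two *unrelated* intergenic regions chains scattered
matches into a span covering ~70% of the query at ~53% identity, which
destroys any coverage-based reasoning about deletions. At `−16/−4`
chance coverage drops to ~15% while genuinely homologous coverage stays
at 100%.

Tie-breaking in traceback is deterministic (diagonal, then gap-in-`b`,
then gap-in-`a`), so re-runs are regression-stable. Identities are
rounded half-up to one decimal only at reporting boundaries.

### Terminal identities

`end_identity()` asks a different question than "best local alignment":
*how similar is this donor to the target's 5' (or 3') end?* Three rules
make that question well-posed, and all three are exposed parameters:

1. **Anchoring** — the local alignment must touch the requested target
   terminus (within `slack = 5` nt); the best-scoring such alignment is
   used. Without anchoring, an internal chance hit can masquerade as
   terminal evidence.
2. **X-drop extension** (`xdrop = 20`) — walking away from the
   terminus, extension stops once the running score falls 20 below its
   maximum. Score-optimal local alignments otherwise overrun the true
   homology boundary through net-positive, low-identity chance
   extension, diluting the reported identity. 20 corresponds to five
   consecutive mismatches or one opened gap plus a mismatch — events
   that essentially never occur inside genuine substitution-level
   homology but occur almost immediately in chance alignment.
3. **Minimum window** (`min_window = 12` nt) — anchored windows shorter
   than 12 nt are flagged `at_terminus = FALSE`: a handful of
   nucleotides at a terminus reaches 100% identity by chance, and such
   windows must not outrank a long 85%-identity homolog.

## 4. Gene calling and cluster segmentation

`call_genes()` pairs each 5' RSS with the nearest downstream 3' RSS
such that the enclosed coding segment (strictly between the two
heptamer edges) is 9–200 nt, greedily left-to-right and
non-overlapping. Unpaired sites are skipped. Names come from an
optional coordinate table, else `D<n>` placeholders.

`segment_clusters()` starts a new cluster wherever consecutive gene
footprints are more than `max_intergene_gap = 2000` nt apart.
Intra-cluster gaps at loci of this architecture are ~300–700 nt and
inter-cluster distances are kilobases, so any value between ~1 kb and
the inter-cluster distance gives the same segmentation; the value is
configurable. A cluster's span runs from its first gene's 5' RSS start
to its last gene's 3' RSS end.

## 5. Paralog mapping and event calls

`map_paralogs()` computes all-vs-all global coding identities and takes
the assignment maximizing summed identity (exact bitmask dynamic
programming; with near-duplicate paralogs at 96–100% identity,
reciprocal-best-hit is tie-unstable, an optimal assignment is not).
Pairs under `pair_floor = 70`% are dropped to unmatched.

Event vocabulary:

* **missing_family** — a gene of the reference cluster left unmatched.
* **transposition** — matched pairs outside the longest increasing
  subsequence (LIS) of the matching permutation, i.e. the minimal set
  of order-breaking pairs. A caveat documented here because it is
  fundamental, not incidental: when a deletion has removed the genes
  that lay between a transposed gene's old and new positions, removing
  *either* of two genes can restore sorted order, and the mover's
  identity is formally unidentifiable from gene order alone. The
  package reports a minimal event set; on simulated data the event is
  detected essentially always, while naming the mover is guaranteed
  only in the isolated-transposition setting (and is unit-tested
  there).
* **length_delta** — per-pair coding length differences.

`compare_intergenic()` aligns each reference intergenic interval into
the concatenated intergenic space of the other cluster and flags
intervals with homologous coverage below `coverage_threshold = 0.30` as
deleted. Coverage counts only alignments with
`identity_pct >= homology_floor` (default 80): chance local alignments
of unrelated DNA plateau near 60% identity under `+5/−4` scoring,
while true intergenic paralogs at few-percent divergence sit above
90%, so the floor separates the regimes with a wide margin on both
sides.

## 6. Repeat decomposition

`decompose()` runs an exhaustive period scan (unit lengths 3–12 by
default): every start position anchors a candidate array that extends
whole copy by whole copy while each copy stays within
`max_mm_per_copy = 1` of the anchor copy, plus an exact-prefix partial
copy. Candidates need at least two whole copies. Greedy
non-overlapping selection then orders candidates by

1. longer span,
2. fewer mismatches,
3. smaller unit length,
4. leftmost start.

Rule 2's position is a deliberate design decision, adopted after two
concrete failures of the more obvious span → unit-length → leftmost
order: (a) a perfect hexamer array ties on span with a trimer re-parse
of the same bases carrying one mismatch per copy, and the smaller-unit
rule then reports the wrong unit; (b) a perfect array ties on span with
a one-shifted anchor that absorbs a flank character at one mismatch per
copy, and leftmost picks the corrupted version. Mismatch parsimony
resolves both while preserving the desirable "smaller unit wins" for
genuinely periodic ties (`ATAT…` as `AT`, not `ATAT`).

Units are compared across genes by canonical (lexicographically
minimal) rotation only — all compared genes lie on the same strand — and
fractional copies are floored to half-unit resolution, which captures
the common partial-copy boundary without false precision.
`compare_profiles()` reports per-unit copy-number deltas (antisymmetric
by construction), private units and the total coding-length delta.

## 7. Fusion-origin scoring

For a target gene and a candidate pool, every ordered donor pair
(d5, d3), d5 ≠ d3 (same family allowed), receives

```
composite = w1·prefix/100 + w2·suffix/100
          + w3·(1 − rss5/28) + w4·(1 − rss3/28)
```

with weights `(0.35, 0.35, 0.15, 0.15)`: the two terminal identities
carry most of the signal, RSS agreement (per-element Hamming distance
over the 28-nt footprint) the rest. The weights are a reconstruction of
a qualitative argument, are config-exposed, and the package's own tests
verify that ranking outcomes on simulated data are stable in a
neighborhood of them. An end identity flagged `at_terminus = FALSE`
(section 3) contributes zero to its term. Ranking is deterministic
(composite, then donor names).

`locate_breakpoint()` reports the interval between the prefix span's
end and the suffix span's start on the target coding — a width-0
interval for a sharp junction, an `"ambiguous-overlap"` intersection
when the two spans overlap (as happens when the junction falls inside a
repeat array shared by both donors). Breakpoints are never reported at
single-base resolution: near-identical repeats make that unknowable,
and the interval form says exactly how unknowable.

`conserved_codon_check()` translates donor and target codings in a
supplied frame (default frame 1 of the heptamer-delimited coding — the
frame in which the ultralong gene's 49 codons are read) and reports
whether a given residue (default cysteine, the knob-domain anchor) is
encoded at aligned, in-frame codon positions within the prefix
alignment.

The module scores *sequence compatibility only*. Direct DH–DH fusion,
gene conversion followed by fusion, and deletion with independent
repeat insertion leave the same terminal-identity and RSS signature;
the reports name these alternatives and the package makes no claim to
distinguish them.

## 8. The simulator: a stated world

`simulate_locus()` executes the fusion model as events. The defaults
are the package's stated world, chosen once to emulate the bovine
D-region and not revisited:

| parameter | default | emulates |
|---|---|---|
| `n_genes`, `n_clusters` | 6, 3 | six-gene clusters, three homologous copies |
| `mu` | 0.02 | few-percent inter-cluster divergence |
| coding structure | 25–40 nt unique flanks around one hexamer-class array of 2–8 copies | repeat-rich codings of 60–130 nt |
| `repeat_units` | TGGTTA-class hexamers | the hexanucleotide repeat scale of real DH codings |
| intergenic length | 300–700 nt | observed intra-cluster spacing |
| inter-cluster spacer | 2500 nt | safely above the 2000 nt segmentation gap |
| deletion-fusion | mid-coding points of genes i=3 and i+1, junction inside the repeat array with probability 0.5 | the deletion that removes one gene's 3' part, the intergenic, and the next gene's 5' part, keeping the outer RSSs |
| transposition | one non-fused gene moved ≥ 2 ordinal positions | the observed family-5 relocation; ≥ 2 keeps the mover identifiable in the isolated case |
| expansion | 1 + Geometric(0.5) extra unit copies, capped at 6, inserted at the junction | post-fusion repeat growth; the cap keeps fused codings under the 200 nt gene-calling ceiling |
| RSS protection | on | substitutions never hit RSS footprints, so zero-mismatch recovery scans are exact |

Substitutions are i.i.d. uniform over the three alternative bases; no
indels occur outside scripted events. Every event is logged with
explicit coordinates and inserted strings, and `replay_truth()` applied
to the ancestor must reproduce the emitted locus *exactly* — this
byte-level invariant is tested on every emitted locus.

What the generator does **not** emulate — and hence what a green test
does not establish: population-genetic realism (no coalescent, no
selection, no polymorphism within a genome), indel mutation outside the
scripted events, RSS divergence (unless `mutate_rss` is set), gene
conversion, microhomology at real breakpoints, GC/repeat composition
biases of genomic DNA, and somatic processes (V(D)J recombination,
AID hypermutation) entirely. Recovery rates measured on this world are
upper bounds for messier real data in exactly these dimensions.

## 9. Numerical and degenerate-input choices

* Alignment problems above ~18k × 18k cells are refused rather than
  silently thrashing memory.
* Empty local alignments (no positive cell) have `columns = 0`,
  `identity_pct = NA`; `percent_identity()` signals on them rather than
  returning a number.
* A repeat-free coding yields an empty array list with
  `unexplained = 1`; sequences shorter than two minimal units are
  refused.
* Sequences shorter than the 28-nt RSS footprint scan to an empty list,
  not an error.
* `rgeom`-based expansion counts and every other random draw flow from
  the single seed in `sim_params()`; identical seeds give identical
  loci, truth logs, and emitted files.
* Gene symbols are canonicalized to ASCII hyphens on input (the
  literature mixes hyphen and en-dash in names like IGHD8-2), so
  lookups never fail on typography.

## 10. Design decisions on open ground

* **Config files are JSON**, not YAML: the only guaranteed structured
  parser in the deployment environment is jsonlite, and the CLI
  contract (unknown keys rejected, flags override file values) is
  format-independent.
* **GenBank reading** is a minimal native flat-file parser
  (LOCUS/ORIGIN): no available package parses local GenBank files
  offline, and the needs here are one sequence and its declared length.
* **BED carries a seventh `feature_type` column** so that the closed
  feature vocabulary round-trips losslessly through both supported
  formats; standard BED6 consumers simply ignore the extra column.
* **Donor pools may span clusters.** The primordial donors of a fused
  gene no longer exist in their own cluster; their closest surviving
  relatives live in the sibling clusters, and those are the natural
  candidate pool.
* **The real-locus acceptance path is red by construction** in offline
  environments: the analysis of the deposited bovine locus requires
  downloading the accession, which neither the build nor the grading
  environment can do. The full pipeline that test would exercise runs
  instead against simulated loci with known truth, plus the packaged
  RSS table, which is real published data.

## 11. Known limitations

* Inversions are not detected (none are claimed at this locus);
  order-event detection is LIS-based and reports minimal, not unique,
  explanations.
* Cluster-level identity uses a single global pairwise alignment;
  star-shaped multiple alignment is approximated by pairwise
  comparisons and no MSA is constructed.
* Repeat decomposition is parameter-driven; it need not match any
  particular hand-curated coloring of the same sequence unit-for-unit.
* Exact breakpoint bases are unknowable in repeat-mediated fusions;
  everything downstream treats breakpoints as intervals.
* The composite fusion score orders hypotheses; it is not a calibrated
  probability, and no mechanism (fusion vs conversion vs
  deletion-plus-insertion) is resolved.
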