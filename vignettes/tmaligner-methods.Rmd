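---
title: "Region-aware progressive alignment of transmembrane proteins: methods"
author: "tmaligner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-aware progressive alignment of transmembrane proteins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmaligner)
```

## The problem and the approach

Alpha-helical membrane proteins alternate between short hydrophobic
membrane-spanning helices (TM) and soluble loops on the cytoplasmic
("inside") and non-cytoplasmic ("outside") faces. Within a family, the
helices are strongly conserved in length and composition while loops absorb
most insertions and deletions. A generic global aligner has no notion of
this structure and will happily pay for a gap inside a helix; the result is
an alignment in which homologous membrane-spanning blocks are broken up.

`tm_align()` exploits the structure directly:

1. **Topology.** Each sequence is partitioned into TM / inside / outside
   segments, either by the built-in hydropathy predictor (below) or from
   imported TMHMM-format annotations, which take precedence when supplied.
2. **Classification.** Sequences are grouped by TM count; the largest group
   (ties towards the larger count, for richer anchoring) is the *dominant
   class* and seeds the alignment. With `K` helices each member contributes
   `2K + 1` region slots: `loop0, TM1, loop1, ..., TMK, loopK`. Slot pairing
   is by index, which is well defined precisely because the class shares one
   TM count. Sequences with other TM counts are set aside as *off-class*.
3. **Guide tree.** One UPGMA tree is built from fractional 3-mer distances
   on the whole (unsegmented) dominant-class sequences and reused for every
   slot. The merge loop keeps an array of per-row minimum references so each
   merge costs O(N), O(N²) overall, with results identical to the cubic
   textbook algorithm under the deterministic tie-break (lowest row-major
   index pair).
4. **Region-wise alignment.** Every slot is aligned independently by
   progressive profile alignment over the shared tree, using affine-gap
   (Gotoh) dynamic programming. TM slots are scored with the transmembrane
   matrix, loop slots with the soluble matrix (one matrix can be forced
   everywhere). Empty slot strings — a sequence that starts directly with a
   helix has an empty `loop0` — are legal and become all-gap rows.
5. **Stitching.** The slot alignments are concatenated in topology order.
   Before concatenation, each member's degapped slot rows are located inside
   its original sequence by Wu-Manber multi-pattern matching and checked to
   form the unique contiguous tiling chain; any failure aborts the run,
   since it can only mean corrupted segmentation. Columns inherit their
   slot's label, so TM columns of the seed contain TM residues or gaps only
   — helices are never disrupted, by construction.
6. **Off-class merging.** Each off-class sequence is aligned to the seed
   profile as a whole sequence, one at a time, ordered by increasing 3-mer
   distance to the seed's degapped consensus (a deterministic
   closest-first order). Profile alignment only ever inserts whole gap
   columns, so the relative gap structure of the seed is preserved.
7. **Reporting.** All-gap columns are stripped (only at the very end, so
   intermediate widths stay consistent across slots), and the consensus,
   per-sequence TM report, guide tree and configuration echo are attached
   to the result.

Every stage that produces an alignment asserts the round-trip invariant:
removing the gaps of any row must reproduce the input residues exactly.

## Scoring model

Three substitution matrices are packaged. `BLOSUM62` is the standard
half-bit table. `GONNET250` is the Gonnet et al. (1992) PAM250-equivalent
table with entries scaled by 10 and rounded, so all dynamic programming is
integer-exact and traceback ties cannot depend on floating-point noise.
The `PHAT` selection scores TM blocks; the packaged table is a clearly
labelled synthetic stand-in (see `inst/extdata/PHAT_synthetic.mat`): a
deterministic BLOSUM62-derived construction that rewards exchanges within
the apolar helix core set {I,L,V,M,F,A} by +1 and penalises
hydrophobic-polar cross pairs by −1, mirroring the substitution behaviour
of membrane-embedded blocks. Users holding the published PHAT(75/73)
matrix can load it with `read_score_matrix()` and pass it directly. `X`
scores 0 against everything.

Gaps are affine: a gap of length `L` costs `gap_open + (L − 1) ×
gap_extend`, the opening penalty charged once per gap — the dominant
convention among progressive aligners. Defaults are `gap_open = 8`,
`gap_extend = 1`, with the TM matrix defaulting to `PHAT`. Whether the
original method applied its TM matrix to loops as well is not documented;
here the per-region choice is configurable, defaulting to
BLOSUM62-for-loops on the argument that loops are soluble-like sequence.
Terminal gaps are penalized like internal ones: region strings are short,
and free end gaps would let residues drift across slot boundaries before
stitching.

The profile-profile column score is the average substitution score over
all residue pairs between two columns; gap symbols contribute zero to the
numerator while the denominator stays `members(p) × members(q)`. Gap
penalties are not rescaled by column occupancy. Two single-row profiles
therefore reduce exactly to pairwise alignment.

The DP uses the Gotoh three-layer recurrence (match, gap-in-A, gap-in-B).
Each layer carries its own branch matrix of per-cell transition codes, the
`(m+1) × (n+1)` record from which one optimal alignment is recovered
without rescoring; a single-layer traceback cannot recover affine optima
correctly. Ties prefer diagonal over up over left, biasing towards
substitutions and making output deterministic.

## The hydropathy predictor

The built-in predictor is a functional substitute for an external
HMM-based tool, with four parameters:

| parameter | default | meaning |
|---|---|---|
| `window` | 19 | averaging window (residues), a typical helix span |
| `threshold` | 1.6 | windowed Kyte-Doolittle score called membrane-embedded |
| `min_helix_len` | 15 | shortest reported helix |
| `max_helix_len` | 35 | longest reported helix |

Maximal runs of positions whose windowed mean reaches the threshold are
helix *cores*. Window averaging has two systematic artefacts that the
conversion from cores to helices must undo:

* **Edge erosion.** A true helix's core is eroded at each end by up to
  `(window − 1)/2` positions, so a single helix of length `max_helix_len`
  can produce a core of at most `max_helix_len − (window − 1)/2` (26 at
  defaults). Cores longer than that must span more than one helix and are
  split recursively at their least-hydrophobic raw-index position — the
  buried loop residue — which itself reverts to loop, so parts never abut
  (adjacent same-label segments are not representable in a topology
  annotation).
* **Boundary smear.** Core edges both fall short of and occasionally bleed
  past the true helix ends. Each core edge is therefore trimmed back over
  residues whose *raw* Kyte-Doolittle value is below the threshold, then
  extended over contiguous residues at or above it, clamped to
  `max_helix_len` and to at least one loop residue between helices. Cores
  still shorter than `min_helix_len` are padded one flank position at a
  time, higher-profile side first. This two-stage core-plus-refinement
  scheme is what makes helices ~18 residues long recoverable within a few
  residues despite the 19-residue window.

The price of the split rule is that genuine helices longer than
`max_helix_len − (window − 1)/2` would be split in two; with the default
target range of 18–25-residue helices this does not arise.

Hydropathy cannot orient a protein, so loops alternate
`outside`/`inside` starting with `outside` at the N terminus. The
alignment treats the two loop classes symmetrically — orientation affects
only the TM-Info report. When every input has zero predicted helices the
pipeline warns and falls back to plain progressive alignment.

## The synthetic family generator

`simulate_family()` generates the verification conditions: a common
ancestor with `K` helices (lengths 18–25) separated by loops (lengths
5–40), helix residues drawn from an apolar pool weighted towards I/L/V/F
(mean Kyte-Doolittle ≈ +3.6, as in real TM helices) and loop residues from
a full-alphabet pool enriched in G/S/T/A/P with charged residues present
(mean ≈ −1.5, typical of soluble segments). Descendants apply i.i.d.
substitutions — helix substitutions stay inside the hydrophobic pool, so
helices remain helices — and at most one indel per loop per descendant
(probability 0.3, geometric length with mean 3), never inside helices.
The default substitution rate of 0.3, with replacement drawn from the
pool excluding the current residue, gives `(1 − r)² + r²/|pool| ≈ 0.50`,
i.e. the intended ~50% mean pairwise identity regime; the measured value
across seeds is within a percent of that. The true alignment is built
from the edit history (each member's insertion gets its own columns), so
TM columns of the truth are indel-free and the recorded topology is exact.
One private RNG stream per family, restored afterwards: the same seed is
byte-reproducible and never perturbs the caller's RNG.

What the generator does *not* emulate: tree-structured evolution (all
descendants radiate independently from the ancestor), rate heterogeneity
across sites, signal peptides, re-entrant or half helices, and loop
composition drift. Passing the recovery tests therefore shows the machinery
is correct under the stated model, not that accuracy transfers to any real
family.

## Numerical and degenerate-input choices

* Integer scoring throughout (GONNET pre-scaled ×10); profile column
  averages are exact small rationals, and pairwise scores re-score exactly.
* UPGMA merge ties: lowest `(i, j)` pair in row-major order. Traceback
  ties: diagonal > up > left. Consensus ties below the majority threshold
  give `X`; at equal top frequency letters beat the gap symbol.
* Empty sequences in pairwise alignment produce pure-gap alignments with
  cost `gap_open + (L − 1) × gap_extend`; width-zero profiles merge by
  prepending all-gap rows at zero cost.
* k-mer distance clamps `k` to the shorter sequence; the denominator is
  `min(len) − k + 1`, so identical sequences are at distance 0 and
  k-mer-disjoint ones at 1.
* Annotation files use 1-based inclusive coordinates (TMHMM dialect);
  internally everything is 0-based half-open, converted only in the I/O
  layer. The gap character is `-`; `.` is normalised on input.
* Input cap `max_seqs = 5000` mirrors the public server's load-protection
  default and is overridable (`0` disables it); it is not an algorithmic
  limit.

## Verification problem sizes

The shipped test-and-acceptance harness checks, at sizes chosen to keep a
full run in well under a minute per property: pairwise DP against
exhaustive enumeration of every affine-gap alignment (100 random pairs,
lengths ≤ 6); Wu-Manber scanning against an all-occurrence naive scanner
(200 random pattern-set/text cases, texts to 2000 characters, both block
sizes); row-minimum UPGMA against the cubic reference (50 random matrices,
N ≤ 20) and against `hclust` average linkage; and, on 20 seeded
seven-helix families of eight sequences at ~50% identity, end-to-end
recovery (sum-of-pairs vs the recorded truth: mean ≥ 0.9, minimum ≥ 0.8),
zero TM-column purity violations, byte-exact round trips, and ≥ 95% of
planted helices recovered with both boundaries within 3 residues.

## Known limitations

* The dominant-class seed assumes the family really shares a TM count;
  heavily mixed inputs degrade to whole-sequence profile merges for
  everything outside the largest class. How the original method merged such
  sequences is undocumented; closest-first whole-sequence merging is this
  package's choice.
* Loop orientation labels are conventional, not predicted.
* No iterative refinement or consistency library: the progressive result
  is final.
* The packaged TM matrix is a synthetic stand-in, not the published
  PHAT(75/73) table (which can be supplied by the user).
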