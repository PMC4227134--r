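---
title: "Strictly valid structured motif extraction: model, algorithm, and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strictly valid structured motif extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifbox)
library(tibble)
```

## The problem

Composite regulatory elements — pairs or triples of conserved "boxes"
separated by spacers of loosely constrained length — are a recurring
structure in promoter regions: two transcription-factor contact sites a
helix-turn apart, a -35/-10 promoter pair, a dyad with a variable loop. A
*structured motif* models this as an ordered tuple of β boxes, box *t*
having length *k_t* and an error tolerance *e_t*, with the number of
letters strictly between consecutive boxes constrained to an interval
[*dmin_t*, *dmax_t*]. A motif is *valid* for a dataset of *N* sequences if
it (*e_t*)-occurs — every box within its Hamming or edit tolerance, every
spacer length inside its interval — in at least *q* of them (the quorum,
given either absolutely or as a ratio *q′* of *N*).

motifbox restricts attention to **strictly valid** motifs: valid motifs
that additionally occur *exactly*, at least once, somewhere in the input.
The restriction is mild on realistic datasets — a motif satisfying all box
and spacer constraints yet never once appearing verbatim is combinatorially
unlikely — and it changes the algorithmics completely: every candidate
motif is now a tuple of literal windows of some input sequence, so
extraction reduces to *fixed-length approximate string matching* between
sequence pairs, with no enumeration of the exponential candidate space
Σ^(k₁+⋯+k_β).

## The pairwise reduction

For an ordered pair (x, y) and window length *k*, the matrix **M** (Hamming
model) stores at cell [i, j] the distance between the window of *y* ending
at position *i* and the window of *x* ending at *j*; windows of unequal
length (i or j < k off the diagonal) get an infinite sentinel, represented
as *k* + 1. Cell [i, j] ≤ *e* means "window *j* of *x* e-occurs in *y*
ending at *i*". The edit-model matrix **D** stores instead the minimum edit
distance between *any* factor of *y* ending at *i* (free start, empty
factor allowed) and the window of *x* ending at *j*.

Three engines compute these matrices and are tested cell-for-cell
equivalent:

* **naive** — the per-cell definition, in R; the reference semantics.
* **sliding** — the default. Hamming cells follow the O(1) diagonal update
  `M[i,j] = M[i-1,j-1] + [y_i ≠ x_j] − [y_{i−k} ≠ x_{j−k}]`; edit columns
  come from per-window dynamic programming whose final columns are collated
  into **D** (windows j ≥ k take the full-window column of their own table,
  columns j < k the prefix columns of the first window's table). The
  collation is done by final *column* because only that orientation
  reproduces the stated cell semantics of **D**.
* **bitparallel** — windows packed into 64-bit words: a shifted mismatch
  mask with popcount for Hamming, a Myers-style bit-vector recurrence (the
  semi-global variant whose column 0 stays 0) for edit. Requires k ≤ 64.
  The word-parallel algorithms from the literature are cited rather than
  specified in full detail, so this engine is validated against the naive
  definition rather than treated as normative.

Single-motif extraction (β = 1) runs one matrix per ordered pair, self-pairs
included — a motif's own source sequence counts toward its quorum, which the
two-string worked example below requires. A window string is reported if it
e-occurs in ≥ *q* distinct sequences; identical window strings from
different positions collapse to one report, and weighted support counts
distinct (sequence, end position) occurrence endpoints.

## Merging boxes under gap constraints

For structured motifs, β matrices are computed per pair (one per *distinct*
box length — boxes sharing *k* share a matrix) and per-box occurrences are
merged. An *anchor* is a cell [i, j] of the first box's matrix with value
≤ e₁ and i, j ≥ k₁. From an anchor, a candidate is a pair of gap vectors
(g_x for the source string, g_y for the target), each component within its
interval; the candidate survives if for every interval *t* the cell

&nbsp;&nbsp;&nbsp;&nbsp;[ i + K_t + Vy_t , j + K_t + Vx_t ] ≤ e_{t+1},

where K_t = k₂+⋯+k_{t+1} and Vx_t, Vy_t are the prefix sums of the gap
vectors; out-of-range cells fail. Each survivor names a strictly valid
motif — the windows of *x* at the source offsets, which are literal
substrings of *x* with spacers g_x — together with one occurrence in *y*
at the target endpoints.

With δ the widest interval span and γ = β − 1, trivial enumeration touches
γ·δ^(2γ) cell references per anchor. But the checked cells depend only on
the *prefix sums* of the gaps, which form contiguous arithmetic
progressions p_t = [Σdmin, Σdmax]; only Σ|p_t|² distinct cells exist, and
each failing cell invalidates every candidate routed through it. The
progressions and the cell-to-candidate association depend only on the
instance, so `build_progressions()` computes them once. For intervals
[1,2] and [4,5], p₁ = {1,2} and p₂ = {5,6,7}: 13 distinct cells stand in
for 32 references over 16 candidates, and a single failing interval-1 cell
at offsets (2,1) rules out 4 candidates at once. `mode = "pruned"`
(default) evaluates the distinct cells and looks candidates up;
`mode = "trivial"` walks every candidate's cells; both return identical
reports and the test suite asserts it on randomized instances.

Anchors are enumerated per pair in a fixed deterministic order (the stored
matrix's memory order, so the transposed orientation of a pair scans
contiguously); reports are ordered lexicographically by motif string, so
output never depends on pair scheduling — ordered pairs are independent
work units.

### Gap semantics

The spacer length is the number of letters strictly between consecutive
boxes: start(box_{t+1}) − end(box_t) − 1 ∈ [dmin, dmax]. The worked
two-string example forces this reading — the box AAA ends at target
position 5, TAT starts at position 7, and the arrangement is reported
under the interval [1,2] (spacer length 1), not [2,2].

### The edit model and structured motifs

Hamming is the reference model for structured extraction. Under the edit
model a cell of **D** certifies only the *end* position of the matching
factor, not its length, so a passing cell cannot pin the spacer length
exactly. `extract_structured()` with `model = "edit"` is therefore an
explicitly documented approximation: the merge widens the checked rows for
box *t*+1 to ± e_{t+1} around the nominal endpoint, and reported gap
lengths in the *target* sequence carry up to *e* letters of slack per box
(source-side gaps are exact — they come from literal windows). With e = 0
the edit and Hamming models provably coincide, which the tests exercise.
The direct `occurrence_scan()` uses the same nominal-endpoint convention so
the two paths stay comparable.

## Worked example

```{r example1}
ds <- tibble(id = c("s1", "s2"), seq = c("CAAACCTTT", "CGAAAGTAT"))
ins <- parse_instance("(3,0)[1,2](3,1),2", quorum_kind = "absolute")
M <- flasm_matrix("CAAACCTTT", "CGAAAGTAT", k = 3)
matrix_cell(M, 5, 4)   # AAA aligned exactly
matrix_cell(M, 9, 9)   # TTT vs TAT, one mismatch
extract_structured(ds, ins)
```

Both reported motifs are strictly valid (AAA[1,2]TTT occurs literally in
the first sequence with spacer 2, AAA[1,2]TAT in the second with spacer 1)
and each e-occurs in both sequences, meeting q = 2.

## Significance ranking

Support (sequences containing the motif) and weighted support (total
occurrences) are descriptive; to rank motifs, `motif_zscores()` recomputes
both by direct occurrence scan in R randomized datasets and standardizes
the observed counts: z = (observed − mean)/max(sd, floor). The classic
post-analysis tool this emulates describes its measure only as occurrence
frequency "in a random subset of the input dataset", so two readings are
implemented: a per-sequence letter shuffle (composition-preserving; the
default, because it keeps N and sequence lengths fixed and so compares
like with like) and sequence subsampling (`randomization = "subsample"`).
Defaults: R = 50 replicates; sd floor 1 count, so a motif never seen in
randomized data gets the finite, interpretable z = observed count. Ranks
are assigned by descending z, ties broken lexicographically by motif
string, separately for support and weighted support. Exclusion filtering
(`filter_excluded()`) generalizes dropping motifs that are also common in
a second sequence set (e.g. coding regions).

## The implantation benchmark

`implant_motifs()` reproduces the planted-motif protocol: draw consensus
boxes uniformly; select q target sequences uniformly without replacement;
in each target, build an instance by choosing exactly e_i positions per box
and replacing each with a letter drawn uniformly from the *whole* alphabet
(so the realized error count can be smaller — the protocol's literal
wording; `mutation = "strict"` forces true mismatches), drawing spacer
lengths uniformly in their intervals with uniform letters, and overwriting
a uniformly chosen factor of the right length. `generate_background()`
supplies i.i.d. uniform backgrounds so no external sequence download is
needed; any user FASTA can serve as background instead. A uniform
background lacks the repeat structure and composition bias of real
upstream regions, so chance-motif counts here are conservative — passing
benchmarks demonstrate correctness of the machinery, not performance on
genomic sequence.

Two collision policies: `"reject"` (default) resamples the replacement
window so implants never overlap, keeping ground truth exact — when a
selected sequence has no free window, another sequence with space is drawn
in its place; `"overwrite"` places windows anywhere and may destroy
earlier implants (the protocol text does not discuss overlaps; the intact
ground truth is what the identification count is measured against).

The testable core: when some implanted instance equals its consensus
exactly — always true with all e_i = 0 — the consensus is strictly valid
and e-occurs in all q targets, so extraction *must* report it. With
e_i > 0 under the redraw rule, an instance equals its consensus with
probability Π (redraws per box), e.g. (1/4)·(1/4) = 1/16 per target for
two boxes with e = 1 on DNA; identification of a given motif then fails
with probability (15/16)^q. This is why the benchmark's dataset size
matters: the quorum ratio 7% ties q to N, and q ≈ 75 (N = 1062, the
protocol's own size — ~226 bp sequences, ~240 KB total) puts the expected
identification near 99/100. The packaged benchmarks therefore run the
100-motif experiment at N = 1062 × 226 bp (a few minutes in the compiled
engine) and the single-motif z-score experiment at N = 300 × 226 bp with
50 shuffle replicates, where the implanted motif's support (≈ 21) towers
over any chance motif's and rank 1 follows.

## Numerical and design choices

* **Coordinates** are 1-based with inclusive intervals throughout, matching
  the x[1..|x|] string convention; report files state this in their header.
* **Quorum rounding**: q = max(1, ceiling(q′·N/100)) — the quorum is a
  lower bound, so rounding up never admits under-supported motifs; a
  `rounding = "floor"` switch exists for compatibility. An epsilon guards
  exact integer ratios against floating-point drift.
* **Sentinel infinity** is k + 1 for Hamming matrices (strictly above any
  attainable window distance); it never reaches reports.
* **Deduplication**: motifs by their rendered string (boxes joined by
  `[dmin,dmax]`); occurrences by full per-box endpoint tuple per sequence;
  the retained source location is the first seen in scan order.
* **Alphabet**: Σ = {A,C,G,T} by default, any declared alphabet accepted
  (the method is alphabet-independent); letters outside Σ are rejected at
  input by default, or the offending records skipped. Reverse-complement
  expansion and IUPAC ambiguity codes are out of scope.
* **Problem sizes in the tests**: oracle-equivalence tests run 200+
  randomized instances with N ≤ 5, sequence length ≤ 60, β ≤ 3, e ≤ 2 —
  sizes where the brute-force enumeration oracle (substring loops and
  `utils::adist` only, no shared code with the extraction path) is
  exhaustive yet fast; the two implantation benchmarks run at the sizes
  stated above.

## Limitations

* The structured edit model carries the gap slack described above; for
  exact spacer semantics under indels a different certificate (per-factor
  start tracking) would be needed.
* Support counting is exact but the z-score null (shuffled or subsampled
  background) is a pragmatic reconstruction, not a calibrated p-value.
* Runtime is Θ(N²n²) in matrix cells regardless of k and e — a virtue for
  large k (the suite checks wall time is flat across k ∈ {6,12},
  e ∈ {1,3}) but quadratic in dataset size; for hundreds of megabases an
  index-based method would be preferable.
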