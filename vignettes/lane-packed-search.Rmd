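---
title: "Lane-packed score-only Smith-Waterman search: model, layout and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lane-packed score-only Smith-Waterman search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swlane)
```

## The model

swlane scores a protein query against every sequence of a database with
the Smith-Waterman algorithm under affine gap penalties, reporting only
the maximum score per database sequence (score-only search). Scoring uses
the three-matrix Gotoh formulation with zero boundary conditions; `H` is
floored at zero, so any alignment may start anywhere, and the score is
the maximum `H` over all cells. `E` carries the gap running along the
query direction within the current sweep; `D` carries the gap along the
database direction and therefore needs the previous database position's
values, which is why the streaming engine stores it as a column alongside
`H`.

The engine never computes tracebacks. That is a deliberate design, not a
shortcut: dropping traceback removes the need to retain the matrix, so
one H column, one D column, a running E and the upper-left H carry are
the entire per-lane state. Users who need the actual alignments export
the top hits to FASTA (`export_top_fasta()`) and align that small file
with a conventional full-alignment tool.

### Gap conventions

Published tools disagree on whether the first gap residue costs the
opening penalty alone or opening plus extension. Both are exact affine
schemes; they differ only in the effective opening charge. We default to
`first_gap = "open"` (a gap of length $k$ costs $\alpha + (k-1)\beta$,
so with the default $\alpha=10$, $\beta=2$ a 1-gap costs 10) because it
is the form in which the recurrences are usually written, and expose
`"open+extend"` ($\alpha + k\beta$, the FASTA-suite/ssearch reading)
as a scheme flag so results can be compared against either family of
tools. The frozen worked-example score 18 for
`HEAGAWGHEE` / `PAWHEAE` (BLOSUM62, 10/2) holds under the default; the
same pair scores 17 under `"open+extend"`. Both values were computed with
two independent established aligners before this engine existed and are
pinned in the tests.

### Alphabet and encoding

Profiles score 23 characters per column, so the alphabet is fixed to the
20 standard amino acids plus B, Z and X, in the order
`r paste(aa_alphabet(), collapse = "")`. Encoding is total: letters
outside the alphabet (U, O, J, `*`, ...) map to X, which scores
conservatively rather than erroring — a pragmatic choice for real
databases, which contain occasional nonstandard letters. Three control
codes live above the residue range: `SEQ_TERM` (23) starts a new
alignment, `GROUP_TERM` (24) ends a lane's workload, `PAD` (25) is inert.
Scores are kept in 16-bit unsigned range and saturate at 65535 rather
than wrapping; saturated hits carry a flag, since a saturated score is a
lower bound, not an exact value.

## The packed layout

Database conversion has four steps:

1. **Sort** by decreasing length (stable). Seeding sets with the longest
   remaining sequences puts near-equal lengths in neighboring lanes and
   makes the longest member of each set its first seed.
2. **Concatenate.** Each new set seeds `lanes` (default 16) groups with
   the next `lanes` unplaced sequences. Every group has a content
   capacity equal to the set's target length; a group holding members of
   total length $L$ with $m$ members uses $L + m$ codes (one terminator
   per member, `SEQ_TERM` between members and `GROUP_TERM` last) of its
   $T + 1$ budget. Groups are then filled greedily best-fit-decreasing:
   repeatedly append the longest unplaced sequence whose length plus one
   terminator still fits. Greedy bin-packing is an approximation — an
   optimal packer could occasionally waste less padding — but it is
   deterministic, fast, and reaches zero padding whenever lengths allow.
3. **Equalize.** In `"equal"` mode the target of *every* set is the
   longest sequence in the database, so each lane everywhere sweeps the
   same number of positions and the workload balance ratio (max over mean
   of per-set stream lengths) is exactly 1. `"set-local"` mode, kept as
   the comparison point, targets each set at its own longest member;
   over skewed length distributions this leaves later (shorter) sets with
   less work per lane, which `workload_report()` quantifies.
4. **Interlace.** Group streams are padded with `PAD` to a multiple of
   `subset_length` (default 8) and stored as alternating
   `subset_length`-character subsets per lane, so the 16 lock-step
   readers' next bytes are contiguous (16 lanes x 8 bytes = one 128-byte
   block).

A final partial set is completed with all-PAD lanes. The trailing
pad-to-subset and all-PAD lanes mean the layout can be slightly larger
than the pure content; `verify_roundtrip()` reports the pad fraction, and
deinterlacing plus terminator splitting must recover the input sequences
exactly (as a multiset), which the tests enforce over randomized
databases.

The on-disk format is little-endian with a 4-byte magic, a version byte
and one byte per header field; the sequence index and the descriptions
travel in plain TSV sidecars. The paper-facing parameters are all
configurable (`lanes`, `subset_length`, packing mode) so tests can
exercise degenerate layouts (`lanes = 1` reduces to a plain streaming
scan; `subset_length = 1` interleaves single characters).

## The engine and its oracle

`search_packed()` walks each set's interlaced stream in storage order,
which *is* lock-step subset order, dispatching each window to its lane's
state. Correctness must be independent of that schedule: scores may not
change with `lanes`, `subset_length` or packing mode, or with where a
sequence landed in the layout. This configuration invariance, plus
equality with the independent full-matrix oracle `sw_score_oracle()` for
every sequence, is the package's central correctness property. The
oracle itself is cross-checked against `Biostrings::pairwiseAlignment()`
(an unrelated implementation) on random pairs under both gap
conventions.

Numerical details worth stating: `E` and `D` are floored at zero, which
provably never changes `H` (both only enter `H` through a max that
already includes 0) and keeps all state non-negative for 16-bit storage;
ties in `top_hits()` break by database rank (input order) ascending so
reports are deterministic; duplicate database ids are tolerated
(sequences are verified positionally, not by id).

## The memory cost model

The cost model is static arithmetic, not a simulator: it reports, per
16-lane half-warp per matrix-fill iteration, the transaction count and
byte traffic of the temporary-data accesses under four storage schemes —
scattered 4-byte values (64 transactions of 32 bytes, 2048 bytes, of
which 1792 are waste), 16-bit thread-interlaced values (4 coalesced
32-byte transactions), an interlaced H+D structure (2 x 64-byte), and
two-iteration interlacing (one 128-byte access per iteration on
average, i.e. a read and a write every second iteration). The final
scheme moves 16 times less data and issues 1 instead of 64 transactions.
Transaction sizes are restricted to 32/64/128 bytes, the supported
coalesced access sizes; scattered accesses each pay the 32-byte minimum,
so sixteen scattered 4-byte reads waste `(32-4) x 16 = 448` bytes.
`cache_column_capacity()` is the exact floor form
`floor(cache_bytes / (alphabet x entry_bytes))`; at 8 KB, 23 letters and
1-byte entries it gives 356 columns, the longest query whose profile is
fully cache-resident. Latency hiding, cache replacement and scheduling
are intentionally out of scope — the model reproduces design arithmetic,
not hardware measurements.

## The synthetic generator

No reference database ships with the package, so `generate_synthetic_db()`
stands in for one. Residues are uniform over the 20 standard amino acids
(real composition is non-uniform; uniform is the right null for testing
layout and scoring machinery, not for estimating score statistics).
Three length models cover the cases that matter to the layout:
`"constant"` reproduces the equal-length development benchmark where
packing is trivially balanced; `"uniform"` gives bounded skew for
round-trip fuzzing; `"lognormal"` (defaults `meanlog = 5.56`,
`sdlog = 0.8`, clamped to [2, 35213]) emulates the long-tailed length
distribution of a curated protein database — median near 260 residues,
mean near 360, extremes matching the documented range of such
collections. Generation is seeded and restores the caller's RNG state.
What passing tests on these databases do *not* show: behavior on real
homologous families (synthetic sequences are unrelated, so top-hit lists
are chance-level outside planted queries) and score statistics under
realistic residue composition.

## Validation scales

The test suite checks engine/oracle equality on a 1000-sequence database
(lengths 1-500, query length 250) under all nine
`lanes x subset_length` combinations in {1,2,16} x {1,2,8} and both
packing modes, cross-checks 100 of those scores against Biostrings,
fuzzes the conversion round trip over 200 random databases, and runs the
seeded synth-convert-search workflow end to end with a planted query.
These sizes exercise every packing boundary case (single-lane,
single-character subsets, partial final sets, lanes longer than the
database) while keeping the whole suite in tens of seconds on one CPU;
scores are exact integers, so scale beyond coverage adds nothing.

## Known limitations

* Score-only by design; no traceback, no E-values or bit scores — raw
  Smith-Waterman scores only.
* Protein alphabet only.
* The greedy packer is a heuristic; it guarantees validity and equal
  stream lengths, not minimal padding.
* Databases are packed in memory; chunking collections larger than
  memory is not implemented.
* The cost model is analytic and deliberately ignores caches, latency
  and scheduling.
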