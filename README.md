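# swlane

Score-only Smith-Waterman protein database search over lane-packed,
interlaced databases — a faithful CPU reconstruction of the database
organization and memory-access design used by GPU half-warp aligners,
plus the analytic cost model that motivates that design.

## What problem this addresses

Searching a protein database with the Smith-Waterman algorithm is optimal
but slow, and vectorized/GPU implementations win their speed mainly from
*data layout*: scoring 16 database sequences in lock-step only pays off if
every lane has equal work and the 16 lanes read neighboring memory. This
package implements that whole pipeline in software so the layout and its
correctness can be studied, tested and reused:

* **Database conversion** — sequences are sorted by decreasing length,
  concatenated into *sequence groups* (separated by sequence terminators,
  ended by a group terminator), collected 16 groups at a time into
  *sequence sets* whose group lengths all match the longest database
  sequence (*equal-length sets*), and stored *interlaced* as alternating
  8-character subsets so 16 lock-step readers touch one contiguous
  128-byte block.
* **Score-only search** — a streaming engine advances all lanes of a set
  in lock-step, keeping per lane only a single H column, a D column, a
  running E value and the upper-left H carry (16-bit, saturating), and
  emits each sequence's maximum local-alignment score at its terminator.
  Top hits are reported as TSV and can be exported to FASTA for full
  (traceback) alignment by a conventional tool; traceback itself is out of
  scope by design.
* **Memory cost model** — static arithmetic for half-warp memory
  transactions (32/64/128-byte), coalescing waste, the four-step
  temporary-data bandwidth ladder, query-profile cache capacity and
  workload balance of a packed database.

## The algorithm

Local alignment scores use the affine-gap (Gotoh) recurrences with zero
boundary conditions, for query position *i* and database position *j*:

```
E(i,j) = max(H(i,j-1) - alpha, E(i,j-1) - beta)
D(i,j) = max(H(i-1,j) - alpha, D(i-1,j) - beta)
H(i,j) = max(0, H(i-1,j-1) + s(a_i, b_j), E(i,j), D(i,j))
```

with `H = D = E = 0` on the first row and column, and the reported score
`max_{i,j} H(i,j)`. A gap of length *k* costs `alpha + (k-1) * beta` by
default (`first_gap = "open"`); the FASTA-suite convention
`alpha + k * beta` is available as `first_gap = "open+extend"`. Defaults
are BLOSUM62 with `alpha = 10`, `beta = 2`. Substitution lookups go
through a *query profile*: the matrix reindexed by query position (23
one-byte scores per column), so a database residue code addresses scores
directly, and a 356-column profile exactly fills an 8 KB cache
(`floor(8*1024 / 23) = 356`).

Two independent implementations coexist deliberately: a full-matrix
scalar oracle (`sw_score_oracle()`) and the streaming lane engine
(`search_packed()`). The test suite requires them to agree on every
sequence of randomized databases across lane/subset/packing
configurations, and cross-checks the oracle against
`Biostrings::pairwiseAlignment()`.

## Worked example

Using the bundled command-line script (`system.file("cli", "swlane",
package = "swlane")`), generate a small synthetic database, pack it,
and search it with its own first sequence as the query:

```sh
swlane synth   --out s.fasta --n 40 --model uniform --min 10 --max 60 --seed 3
swlane convert --in s.fasta --out s.packed --lanes 4 --subset 2
swlane search  --db s.packed --query s.fasta --out hits.tsv --export top.fasta \
               --lanes 4 --subset 2 --top-n 5
swlane memreport --db s.packed --query-length 356 --out mem.tsv
```

which prints (logs on standard error):

```
wrote 40 synthetic sequences (1355 residues) to s.fasta
converted 40 sequences (1355 residues) into 7 set(s); pad fraction 0.196
scored 40 sequences (1355 residues, 18970 matrix cells); reporting top 5
memory report for 7 set(s): balance ratio 1.000, final bandwidth ratio 16.0x
```

and `hits.tsv` begins:

```
rank	seq_id	score	description
1	SYN000001	80	synthetic protein length=14 model=uniform
2	SYN000031	19	synthetic protein length=60 model=uniform
3	SYN000007	18	synthetic protein length=40 model=uniform
```

Rank 1 is the query itself (a 14-residue sequence aligning to itself with
score 80); the remaining scores are the chance-level similarity of
unrelated random proteins. The memory report's `balance ratio 1.000` says
every lane in every set sweeps the same number of stream positions —
the point of equal-length sets — and `16.0x` is the modeled bandwidth
improvement of the final temporary-data access scheme over the scattered
baseline. The same workflow is available programmatically via
`cmd_synth()`, `cmd_convert()`, `cmd_search()` and `cmd_memreport()`.

In R, the two worked-example scores the package treats as goldens:

```r
library(swlane)
sch <- scoring_scheme()                       # BLOSUM62, 10/2
sw_score_oracle("AW", "AW", sch)              # 15  (= 4 + 11)
sw_score_oracle("HEAGAWGHEE", "PAWHEAE", sch) # 18
```

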