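---
title: "Bounded-memory read-name collation: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-memory read-name collation: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Coordinate-sorted SAM/BAM files are the working format of most sequencing
pipelines because variant calling wants reads grouped by reference
position. The price is that the two mates of a paired-end template, which
share a read name, are separated in the file. Tasks that need the whole
template — converting alignments back to FastQ for realignment or
assembly, and marking PCR duplicates, which are defined on the coordinates
of *both* ends — must first bring the mates back together. Fully
re-sorting a whole-genome file by name is expensive; `bamcollate` instead
collates mates in a single pass within a fixed memory budget.

The key observation is a model of how far apart mates typically are. If a
position on the reference is covered by `d` reads on average, each of
length `l`, then read ends start at a mean rate of `d / l` per
forward-strand position. The two start points of a template of length `t`
lie `t - l` positions apart, so the expected number of alignments between
the two mates in the file is

```
E[gap] = (d / l) * (t - l)
```

(`expectedPairGap()`). At typical human whole-genome parameters — depth
45, template length 324, read length 101 — this is about 99 alignments:
most mates are *close*, and a small window of recent records resolves the
bulk of all pairs. The remainder (split pairs on different chromosomes,
high-coverage pileups, orphans) is what the bounded-memory machinery
handles.

## The collation engine

Records stream through three layers (`collate()`):

1. **Collisionless hash table `H`.** A pointer table of `hashSlots` slots
   indexed by a hash of the read name, backed by a ring buffer of
   `ringBytes` bytes that stores the serialized records, plus an ordered
   index of the start offsets of all live records. An arriving record
   either finds its mate at its slot (a pair is emitted and the slot is
   cleared), finds the slot empty (it is stored), or collides with an
   unrelated resident — the resident is evicted to the overflow list and
   the newcomer stored. Storage may first evict additional residents,
   oldest-in-ring-order first, until the gap between the insert cursor and
   the next live offset fits the record. There is no collision chaining:
   memory is fixed regardless of input.
2. **Overflow list `L`.** A two-ended buffer of `listBytes` bytes: record
   bytes grow from the front, fixed-size start-pointer entries (8 bytes
   each here) from the back; the list is full when the two regions would
   meet. When full it is sorted by name *by permuting the pointer
   entries*, newly adjacent mates are emitted as pairs, and the remainder
   is written, in name order, to a temporary run file.
3. **Name-sorted runs and merge.** After the input is exhausted the
   residue of `H` drains through `L`, and the runs are merged with a
   multiway merge; in the merged name-sorted stream the remaining pairs
   are trivial to detect. Paired-flag leftovers are reported as orphans,
   unpaired ones as singles. If `n_H` records resolve inside `H` and
   `n_L = n − n_H` go through `L`, the work is `O(n_H + n_L log n_L)`;
   with a degenerate single-slot table (`hashSlots = 1`) this collapses to
   the `O(n log n)` external name sort, and the test suite checks the
   output is unchanged in that regime.

### Numerical and representation choices

* **Serialized form.** Records in the buffers and run files are held as
  their SAM text line, preceded in run files by a byte-length prefix and
  the record's rank (0-based line number in the source). The read name is
  the prefix of the line up to the first tab, so it is extractable without
  deserializing. The ring buffer and overflow list do exact byte
  accounting on these lengths; instrumentation high-water marks
  (`maxRingBytes`, `maxListBytes` in `CollationStats`) let tests assert
  the budgets are never exceeded.
* **Hash function.** A polynomial rolling hash (base 131) modulo the
  Mersenne prime 2^31 − 1, reduced modulo the slot count. All arithmetic
  is exact in doubles, so the slot assignment is identical across
  platforms and runs.
* **Name order and ties.** Bytewise lexicographic (C-locale radix) order;
  equal names order read1 before read2, then by rank. Pairs are always
  emitted (read1, read2) regardless of encounter order, which makes the
  FastQ output deterministic.
* **Eligibility.** Secondary (0x100) and supplementary (0x800) alignments
  never enter the pairing structures — a name could otherwise carry more
  than two records and pairing would be ambiguous — and are passed
  through in the singles channel. QC-fail (0x200) records participate
  normally; the flag is passed through.
* **Merge fan-in.** At most `mergeFanIn` (default 64) runs are merged per
  pass; larger run counts trigger hierarchical passes. This realizes
  multi-pass merging while respecting the open-connection limits of the
  platform. Each run reader verifies name order as it reads and aborts on
  a corrupt run. Temporary runs are deleted on success; the directory
  honours the `BAMCOLLATE_TMPDIR` environment variable.
* **Defaults.** `hashSlots = 2^16`, `ringBytes =` 16 MiB, `listBytes =`
  32 MiB: at a mate gap of ~100 records the live population of `H` is a
  few hundred records, so these sizes absorb deep pileups and split pairs
  with a wide margin while keeping the total footprint far below a
  typical per-core allowance.

## FastQ conversion

`bamToFastq()` routes each collated category to its own file: mate-1 and
mate-2 files index-aligned by name, an orphan file and a singles file
(created even when empty, for scriptability). Reverse-strand records are
restored to sequencing orientation — bases reverse-complemented with
IUPAC-aware complements, qualities reversed — and emitted Phred+33.
Records storing no sequence (`*`) cannot be represented in FastQ and are
skipped with a warning count. Names are emitted bare by default; `suffix
= TRUE` appends `/1`/`/2`. Output can be gzip-compressed.

## Duplicate marking

Two reads (or read pairs) are duplicates when they map to the same 5'
coordinates. `markDuplicates()` builds, from the collating reader, a pair
list keyed by the lexicographically ordered pair of end coordinates and a
fragment list keyed by single-end coordinates, then:

* per pair-coordinate class, keeps the highest-scoring pair as
  representant and marks both reads of every other pair;
* marks any single-end read or orphan whose coordinate coincides with an
  end of a mapped pair (pair evidence outranks fragment evidence);
* per remaining fragment-coordinate class, keeps the highest-scoring
  entry and marks the rest.

Design decisions where the convention had to be fixed:

* **5' coordinate, unclipped.** Forward reads: leftmost mapped position
  minus leading soft/hard clip; reverse reads: rightmost mapped position
  plus trailing clip. Extrapolating through clips is what makes PCR
  copies with slightly different local alignments key to the same
  coordinate; the simulator's soft-clip mode exists to exercise exactly
  this.
* **Score.** Sum of base quality values, counting only values ≥ 15; a
  pair scores the sum of its ends; absent qualities score 0. The rule is
  isolated behind `fragScore()`/`pairScore()` so it can be swapped.
* **Ties** go to the lowest rank, making the representant deterministic.
* **Ordering of the orphan rule.** Pair-end protection is applied first;
  intra-class competition happens among the fragments that survive it.
* Unmapped records are never marked; pre-existing 0x400 flags are cleared
  before marking, so marking is a pure function of file content and
  therefore idempotent; all reads are compared in one namespace (no
  library or read-group partitioning — a documented limitation).

The two-pass design (pass 1: collate and deduce the duplicate rank set;
pass 2: rewrite flags by rank) follows from the rank-set being complete
only after the whole list has been processed. The rewrite changes only
the FLAG field; every other byte of every record is preserved.

**Hybrid spilling.** The lists live in memory up to `threshold` entries.
On overflow, every in-memory entry at the lowest coordinate (a pair
counts under its left end) is flushed to that coordinate's spill run on
disk and the coordinate is marked for external handling; later entries at
a spilled coordinate bypass memory and append to the run, which therefore
stays internally coordinate-sorted. The final deduction merges memory and
spill runs, so the marked set is invariant to the threshold — an
invariance the tests assert for thresholds 1, 8 and unbounded.

## The simulator and what the tests show

`simulateAlignments()` emulates a coordinate-sorted paired-end experiment
with known ground truth: templates are placed uniformly on synthetic
references at target depth `d`, template lengths are normal
(`tMean`/`tSd`, truncated at the read length), and configurable fractions
become orphans (mate unmapped and absent), split pairs (mates on
different references), single-end reads, or planted PCR-duplicate
clusters (exact coordinate clones of a seed template, cluster size
1 + Poisson(`lambdaDup`), with independently drawn qualities so the
representant is recoverable). Reads are error-free windows of the
reference; qualities are windows of a pre-generated random Phred 2–40
pool. The truth table records, per template, its category, cluster, both
unclipped 5' coordinates and the sequencing-orientation bases and
qualities — enough to validate collation, FastQ round trips and duplicate
marking without any external data.

What the simulator deliberately does *not* model: sequencing errors,
quality-by-cycle structure, indels or soft-clip noise beyond the
coordinate-preserving clip mode, reference bias, optical-duplicate
geometry, multiple libraries. Passing tests therefore demonstrate the
*algorithmic* contracts (partition correctness, conservation, memory
bounds, invariance properties, exact recovery of planted structure), not
robustness to every artefact of real instruments.

Validation problem sizes: the oracle-equivalence suite uses twenty
generated files from about 10^3 to 10^5 records across hash-slot counts
{1, 16, 2^16} and overflow-list capacities {1, 64, 4096} records (the
one-record list on the smaller files, where the number of temporary runs
it induces stays in a sensible file-handle regime); the formula-versus-
simulation check uses a 10^6-base reference at depth 45 (~4.5 × 10^5
records); brute-force duplicate oracles run on files of ≤ ~200 records,
planted-truth recovery on ~1.6 × 10^4 records. These sizes were chosen to
exercise every code path — including eviction, list flushing and
hierarchical merging — at desk scale.

## Limitations

* SAM is parsed and written natively; BAM passes through
  `Rsamtools::asSam()`/`asBam()` conversion rather than a streaming
  binary decoder, so peak throughput targets validation-scale files, not
  production whole-genome runs.
* CRAM, BAM indexing, tag-aware processing, interleaved FastQ, optical
  duplicate subclassification and Picard-format metrics files are out of
  scope.
* Collation assumes at most two primary mates per name (standard
  paired-end data); a name with more primary paired records is resolved
  read1-to-read2 in rank order and the excess reported as orphans.
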