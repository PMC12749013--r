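---
title: "Memory-bounded de novo deduplication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-bounded de novo deduplication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqdedup)
```

## The procedure

`fqdedup` identifies PCR duplicates from sequence content alone. The
sequence-based engine works in two phases:

1. **External sort.** Deduplication units (a read, or a synchronized read
   pair) are buffered until the next unit would push the summed footprint
   past the memory budget; each buffer is sorted by
   `(sequence key, input index)` and spilled to disk as a sorted *run*. The
   runs are then merged back into one globally sorted stream (k-way merge,
   cascaded when more runs exist than may be open at once). Total time is
   *O(N log N)*; buffered data never exceeds the budget.
2. **Single-pass scan.** Because every duplicate relation used here implies
   adjacency (exact matches and prefix groups are contiguous in sorted
   order; the tail-hamming definition is *defined* on sorted adjacency), one
   pass over the sorted stream suffices. The first unit is kept. Under
   `tight` and `loose` each unit is compared against the current *group
   representative* — the first kept unit of its group — and on failure the
   unit is kept and becomes the representative. Under `tail_hamming` each
   unit is compared against its *immediate predecessor*, kept or not.

The fast mode skips sorting entirely: sequences are packed at 4 bits/base
into 64-bit words and a set of packed keys retains first occurrences in
input order. Packed keys are stored in full, never hashed down, so a false
removal is impossible and the kept set equals tight mode's by construction.

### Assumptions

* FASTQ input uses the modern strict 4-line dialect; multi-line FASTQ is
  rejected. FASTA sequences may wrap. CRLF line endings are tolerated on
  input; output is LF.
* Paired files are positionally synchronized; pairing is by position, never
  by read ID. Unequal record counts abort the run (never a silent
  truncation).
* Qualities are opaque payload: they are preserved byte-for-byte and play no
  role in duplicate decisions.
* Comparisons are case-insensitive; the original case, like every other
  byte of id, comment, sequence and quality, is written back verbatim.
* `N` and the other IUPAC ambiguity letters are ordinary symbols: two `N`s
  match each other and nothing else. No special ambiguity handling.

## Duplicate definitions and their consequences

* **tight** — exact, full-length equality. Different lengths are never
  duplicates.
* **loose** — the shorter sequence must equal the prefix of the longer.
  This relation is not transitive across groups and, for paired-end data,
  depends on which file is "left": the sort concatenates left and right
  sequences, so swapping the files changes the sort order, the group
  representatives, and possibly the kept count. The test suite pins a
  three-pair example where the forward orientation keeps one pair and the
  swapped orientation keeps two. This order sensitivity is inherent to
  prefix-based duplicate identity, not an implementation accident.
* **tail_hamming** — equal length and Hamming distance ≤ k between *sorted
  neighbours*. With mismatches allowed, "is a duplicate of" loses
  transitivity: reads A–B and B–C may each differ by one base while A–C
  differ by two. Comparing each read to its predecessor means removal can
  chain (A kept; B removed as neighbour of A; C removed as neighbour of the
  already-removed B). A second pass can therefore remove further reads —
  tail-hamming is deliberately *not* idempotent, and the suite only asserts
  that a repass never grows the output. Tight and loose compare to the
  group representative instead, which makes them idempotent.

Unequal lengths are non-duplicates under tail-hamming, mirroring the tight
rule; Hamming distance is undefined otherwise. With `k = 0` tail-hamming
reduces exactly to tight (asserted on every test dataset), and loose reduces
to tight whenever all reads share one length.

For paired units every definition is applied per mate and must hold for
both; pairs live or die as wholes, so the two output files always stay
aligned.

**Which copy survives?** The sort breaks key ties by original input
position, so the lowest-index member of every duplicate group is retained.
This makes all modes deterministic, makes fast and tight agree on read IDs
exactly, and makes output byte-identical across memory budgets.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `budget` (`memoryBudget()`) | 2048 MiB | Cap on buffered unit bytes during run building. Floor of 16 MiB guarantees progress. Affects run count and speed, never results. |
| `hammingMax` | 0 | Mismatch budget of the tail-hamming definition. |
| `maxOpenFiles` | 128 | Runs merged at once; beyond it, cascaded merges keep within conservative file-handle limits. |
| `chunkSize` | 20,000–40,000 records | Streaming batch size; a throughput knob only. |
| `tmpdir` | `tempdir()` | Where runs live; each pipeline uses a private subdirectory removed on every exit path. |

The footprint charged per unit is the byte length of its text fields plus a
flat 96 bytes per mate. The constant approximates container overhead; the
contract is *bounded, parameterizable* buffering, not byte-exact process
RSS.

## Numerical and representation choices

* **Sort keys.** The single-end key is the uppercased sequence; the paired
  key is `left || 0x01 || right`. The 0x01 sentinel sorts before every base
  letter, so a left mate that is a prefix of another sorts immediately
  before its extensions — the property the loose scan relies on. (R strings
  cannot carry an embedded NUL byte, so the lowest usable byte plays the
  sentinel role.)
* **Byte-wise comparison everywhere.** All ordering uses
  `order(method = "radix")` and a small C helper for strict less-than;
  locale collation would misorder the control-byte sentinel and mixed-case
  data.
* **Run files** are private line-oriented text, one unit per line, fields
  joined by the 0x1F unit separator (a byte that cannot appear in
  well-formed read fields, which never contain newlines and realistically
  never contain control bytes). Line framing keeps reading and writing
  fully vectorized through R's connection layer.
* **Packing table.** Fast mode encodes `A C G T N R Y S W K M B D H V U` as
  codes 0–15, 4 bits per base. A 2-bit code would be denser but could not
  keep ambiguity codes distinct; exactness is the contract, density is
  secondary. The explicit base count disambiguates sequences whose packed
  words coincide (a 15-mer versus the same 15-mer extended by `A`).
* **Degenerate inputs.** Empty files are valid (zero reads in, zero out,
  duplicate percentage reported as 0.00%); empty sequences are legal and
  compare as length-0 strings (an empty read is a loose-duplicate prefix of
  anything); a single unit larger than the whole budget still forms a run of
  its own.

## Disk usage

Run files serialize the same fields as the input minus FASTQ framing
overhead, so a single merge level writes roughly 1.0× the uncompressed
input; the documented bound of about 2× covers the cascaded-merge case, and
consumed runs are deleted the moment they are exhausted so *live* temporary
bytes never exceed that bound either. `scripts/acceptance.R` measures the
ratio on a ~100 MB library under a 16 MiB budget (about 1.02× in this
implementation). The engine's I/O, not its arithmetic, dominates runtime —
the budget trades speed for memory, never changing output.

One pathological case is worth naming: if essentially *all* reads share one
sequence, the merge must hold the records at the current key in memory at
once (equal-key records are released from runs in input order, which caps
but does not eliminate this). Real libraries, and the synthetic ones used
in testing, are nowhere near this regime.

## The synthetic generator

`generateTemplates()` draws template molecules i.i.d. uniform over
`{A,C,G,T}` (at the default length of 100 the chance of any two of 10^5
templates colliding is ~10^-50, so template count is ground truth for
distinct molecules). `amplifyTemplates()` emits one original per template
plus a configurable number of PCR copies, each either

* an **exact copy**,
* a **tail-error copy** — substitutions placed by a position profile that is
  zero over the first 80% of the read and rises linearly to `maxRate` at
  the 3′ end, emulating end-of-read error enrichment (substitution-only, as
  that is what a Hamming comparison can express), or
* a **truncated copy** — 3′-trimmed by a uniform draw, a planted loose-mode
  prefix duplicate.

Every read's template and class land in a tab-separated manifest, which
gives each mode a computable expected outcome: with zero errors and no
truncation, tight keeps exactly the template count; with full truncation,
loose keeps exactly the template count; a copy with one tail substitution is
removable by tail-hamming with `k = 1` but never by tight.

What the generator does **not** emulate: realistic quality strings (it
writes constant `I`), indels, optical-duplicate geometry, UMIs, adapter
contamination, or non-uniform genomic composition. Passing tests therefore
demonstrate the engine's *contracts* — oracle equivalence, budget
invariance, pair atomicity, byte fidelity — on data whose duplicate
structure is known, not end-to-end accuracy on any particular real library
(which, for mismatch-tolerant definitions, has no single ground truth
anyway).

## Verification strategy and problem sizes

Every mode is checked against an independent, deliberately naive in-memory
reference (`oracleSeqBased()`, `oracleExact()`): plain-R loops over the
sorted units using string primitives, sharing no code with the C++ scan.
The suite runs the full streaming pipeline against these oracles on twenty
seeded libraries of 10^4 reads (two of 10^5), single- and paired-end, under
16 MiB, 64 MiB and 1 GiB budgets, alongside unit tests with raw byte-level
budgets small enough to force many runs and cascaded merges. The
temporary-disk bound is asserted in-suite on a ~32 MB library under a
16 MiB budget, and at ~100 MB by the acceptance script. These sizes were
chosen to exercise every code path (multiple runs, cascades, chunk
boundaries) while keeping the default test run fast.

## Known limitations

* Loose mode implements the stated prefix rule; exact output-for-output
  equivalence with other prefix-based tools is not claimed beyond that rule.
* Tail-hamming compares to the sorted predecessor; comparing to a group
  representative instead would remove a different (equally defensible) set.
  The choice honours the definition "adjacent in the sorted file".
* Single-threaded by design; no UMI handling, no optical-duplicate
  detection, no error correction, no SAM/BAM or interleaved-FASTQ input.
* Fast mode's memory grows with distinct-sequence count and cannot be
  bounded.
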