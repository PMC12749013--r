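# fqdedup

Memory-bounded, alignment-free removal of PCR duplicates from single-end and
paired-end FASTQ/FASTA data.

## The problem

PCR amplification during library preparation produces duplicate copies of
template molecules that can make up tens of percent of a sequencing run and
bias any downstream quantification. *De novo* deduplicators identify these
copies from sequence content alone — no reference genome needed — but most
load the whole dataset into RAM, which is prohibitive for large libraries
(Hi-C, whole-genome, RNA–chromatin interaction data). `fqdedup` targets that
gap: its sequence-based engine keeps memory at or below a user-chosen budget
by sorting reads on disk, at the cost of temporary files totaling at most
about 2× the input size.

## The method

**Sequence-based mode** (`runSeqBased()`). Reads are sorted by sequence with
an external merge sort (*O(N log N)*): units are buffered up to the memory
budget, each buffer is sorted by `(sequence key, input index)` and spilled as
a sorted run, and the runs are k-way merged into one sorted stream. A single
pass over that stream then removes duplicates under one of three
definitions:

- **tight** (default) — duplicates are exact full-length matches; reads of
  different lengths are never duplicates;
- **loose** — the shorter read must equal the prefix of the longer
  (FastUniq-style; results depend on paired input file order, an inherent
  ambiguity of prefix-based duplicate identity);
- **tail-hamming** — reads *adjacent in the sorted stream* with equal length
  and Hamming distance ≤ *k* are duplicates, motivated by substitution
  errors concentrating near read 3′ ends. With mismatches allowed,
  "duplicate of" is not transitive, so the removed set is
  algorithm-defined: removal may chain through intermediate reads.

For paired-end data a pair **B** is removed only when *both* its left and
right reads are duplicates of the corresponding reads of the retained pair
**A**. Within a duplicate group the read (pair) with the lowest original
input position is the one kept. Read IDs, sequences and qualities are never
altered.

**Fast mode** (`runFast()`). Exact duplicates only: each sequence is packed
at 4 bits/base into 64-bit words and the first occurrence of each distinct
packed key (pair of keys for paired data) is kept, preserving input order.
Memory cannot be capped in this mode; its kept set is provably identical to
tight mode's.

The package also ships a seeded synthetic-library generator with a
ground-truth manifest (`synthesizeLibrary()`, classes `original`,
`exact_pcr_copy`, `tail_error_copy`, `truncated_copy`) and naive reference
implementations of every mode (`oracleSeqBased()`, `oracleExact()`) used as
independent ground truth by the test suite.

## Worked example

```r
library(fqdedup)

dir <- tempfile(); dir.create(dir)
fq  <- file.path(dir, "library.fq")

# 1000 templates x 5 reads each: exact copies, 3'-substituted copies
# (2% max tail error rate) and 10% truncated copies, shuffled
synthesizeLibrary(fq, templates = 1000, readsPerTemplate = 5,
                  errorRate = 0.02, truncationFraction = 0.1, seed = 42)

out   <- file.path(dir, "dedup.fq")
stats <- runSeqBased(fq, out, spec = comparatorSpec("tight"),
                     budget = memoryBudget(16), tmpdir = dir)
stats
#> DedupStats (tight): 5,000 in, 2,045 kept, 2,955 removed (59.10%)
cat(reportStats(stats), sep = "\n")
#> 5000 reads in, 2045 kept, 2955 removed (59.10%)
#> total_reads=5000
#> reads_kept=2045
#> duplicates_removed=2955
#> percent_removed=59.10
```

Tight mode removes the exact copies but keeps every substituted or truncated
variant as a distinct sequence (2,045 kept from 1,000 templates). The more
permissive definitions fold those variants back into their templates:

```r
runSeqBased(fq, file.path(dir, "loose.fq"),
            spec = comparatorSpec("loose"), tmpdir = dir)
#> DedupStats (loose): 5,000 in, 1,480 kept, 3,520 removed (70.40%)
runSeqBased(fq, file.path(dir, "th.fq"),
            spec = comparatorSpec("tail-hamming", hammingMax = 2),
            tmpdir = dir)
#> DedupStats (tail_hamming): 5,000 in, 1,437 kept, 3,563 removed (71.26%)
packSequence("ACGTN")
#> PackedSeq: 5 bases, 1 word(s)
#>   0x0123400000000000
```

Paired-end runs take two inputs and two outputs:
`runSeqBased(in1, out1, in2, out2, ...)`. A shell entry point with the same
options is installed at `inst/scripts/fqdedup`
(`fqdedup -i in_1.fq.gz -u in_2.fq.gz -o out_1.fq.gz -p out_2.fq.gz
--compare tail-hamming --hamming 2 --mem-limit 2048`).

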