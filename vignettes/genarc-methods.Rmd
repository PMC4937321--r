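---
title: "Schema-driven columnar storage of genomic records: model and methods"
author: "genarc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema-driven columnar storage of genomic records: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarc)
```

## The data model

Sequencing formats such as FASTQ and SAM are text serializations of a
simple underlying structure: a free-text *header* followed by a long run of
structured — and often coordinate-sorted — *records*.  General-purpose
compressors applied to the serialized text mix fields of very different
statistical character (read names, DNA bases, quality scores, integers)
into one stream and lose most of the redundancy a column store would see.

`genarc` takes the column-store view.  A record type is declared once, in a
small meta-language, as a tree of primitives, arrays, nested records and
tagged unions; the declaration is interpreted at run time and decomposed
into homogeneous *column streams* (values, lengths and union tags), each
compressed independently with a codec chosen per field.  Many datasets of
different record types share one block-allocated *container* on disk.

The record declaration is the single source of truth: parsers produce
record values shaped by it, the stream planner flattens it deterministically
and the canonical rendering of the schema is stored with every dataset, so
a container is self-describing.

### The meta-language

```{r schema}
cat(fastqSchemaText())
```

Primitives are fixed-width integers (`u8` … `u64`, `i32`, `i64`), single
bytes (`char`), booleans (`flag`) and three variable-length byte-string
types.  `dna` and `qual` share `string`'s wire encoding but are distinct
types: they mark fields eligible for type-aware adaptors (reference-based
sequence coding, quality binning) and different codec defaults.  `T[]` is
a variable-length array, `T[n]` a fixed one, and `union { a: A; b: B; }`
a tagged choice.  Inline record types `{ f: T; ... }` give nested records a
spelling; named definitions (`Name = type;`) are ordered and may only
refer to earlier names, which makes reference resolution total — the only
possible cycle is a self-reference, reported as such.

A field annotation `@method(level)` selects the stream codec; every stream
inherits the nearest enclosing annotation, and unannotated chains fall
back to gzip level 6 — a safe universal default for a field about which
nothing is declared.  `parseSchema()` / `renderSchema()` are exact
inverses on structure, and rendering is idempotent, which the test suite
checks by round-tripping randomly generated schema trees.

### Stream decomposition

`planStreams()` flattens the type tree with fixed rules (one lengths
stream + one values stream per variable-length field, one u8 tag stream
per union, dotted path prefixes for nesting; see `docs/FORMAT.md` for the
full table):

```{r plan}
planStreams(resolveTypes(parseSchema(fastqSchemaText())))
```

Wire encodings are deliberately plain: little-endian at the declared
width, u32 lengths, 0-based u8 union tags.  Entropy removal is the codec
layer's job, not the serializer's; keeping the wire format trivial makes
`deserializeChunk(serializeChunk(x)) == x` testable by brute force over
random record lists, and conservation (each lengths stream sums to its
values stream's byte count) a mechanical invariant.  Union branches not
taken write nothing to their streams — the tag alone records the choice —
so streams stay homogeneous.  8-byte integers are exact for magnitudes
below 2^53 (they travel through R doubles), which is far beyond anything a
sequencing record holds.

## Codecs

Built-in methods are `raw` (identity), `gzip` (zlib, levels 1–9, default
6), `bzip2` (levels 1–9, default 9) and `lzma` (xz presets 0–9, default
6), implemented against the system libraries so levels are honoured and
output is bit-stable.  The registry is open: `registerCodec()` accepts any
pair of pure byte-to-byte functions plus a level range, so specialized
DNA or quality codecs — or a PPMd implementation, for which no portable
library is available here — plug in without touching the engine.
Compressed blocks carry no self-describing header; the codec spec lives in
the dataset catalog, one per stream.

The stock schemas assign bzip2(9) to base and quality payloads, whose
block-sorting transform handles small-alphabet, high-entropy-per-symbol
data well, and gzip(6) everywhere else; both choices are plain-text
schema fields, so tuning them requires no code.

## The container

A container is three files sharing a prefix: a pre-sized block data area,
a fixed-layout meta file (geometry + one state byte per block: free,
reserved or occupied) and a JSON dataset catalog.  Two block sizes exist
to bound waste: streams fill *big* blocks (default 8 MiB) and their tails
spill into *small* blocks (default 64 KiB).  Allocation is greedy — as
many full big-block payloads as fit, then the minimal number of small
blocks for the tail, or one more big block when small blocks have run
out — and block ids rise from zero, so allocation is deterministic.

Every block's final 8 bytes hold its payload length and CRC32.  Reads
verify every touched block; `verifyContainer()` sweeps all occupied blocks
and attributes corrupt ones to the dataset and stream referencing them.
Detection is the contract — reconstruction of records from a damaged
block is out of scope.  A dataset enters the catalog only after all its
blocks are occupied, so a crashed write leaves only reclaimable reserved
blocks, never a half-visible dataset.  Containers do not grow; the
intended workflow is to size generously and `shrinkContainer()` — which
rewrites only occupied blocks, remaps ids and preserves every dataset
byte-for-byte — before archiving or exchange.

Writers take an advisory lock file; concurrent readers of finalized
datasets need no coordination.  True multi-writer concurrency is
documented as a contract but not implemented.

## The engine: chunks, determinism, sorted keys

Input records are processed in *chunks* (default 50 000 records; every
chunk ends on a record boundary).  Per chunk, adaptors run in order, the
chunk is serialized, and each stream's payload is compressed
independently — which is also the parallelism unit: chunks may be
compressed by several worker processes, but results are committed in
input order, so container bytes are a pure function of input and
configuration regardless of worker count.  The suite asserts byte-identical
containers for 1 versus 4 workers.  Any worker failure abandons the whole
job before the catalog is touched.

When a key function is supplied (for SAM: the `(reference index,
position)` tuple, with unmapped records assigned the sentinel index
`n_refs` so they sort last), the engine validates global sort order —
reporting the first offending record — and stores the first key of every
chunk in the descriptor.  `queryRange(lo, hi)` then bisects these samples
to the minimal chunk interval that can contain the inclusive key range,
decompresses only that interval and filters exactly.  With one sample per
chunk the located interval can exceed the true matching chunk set by at
most two chunks, and the two binary searches use at most
`2*ceil(log2(n_chunks)) + 2` key comparisons — both bounds are asserted in
tests against a linear-scan oracle, with comparisons counted at 1, 2, 64
and 1024 chunks.  Chunk granularity is the design choice here: finer
(per-block) sampling would shave at most one chunk's worth of excess
decompression while complicating the descriptor; record-level indexes are
a non-goal.

## Stock formats and adaptors

FASTQ and SAM parsers are strict about structure (lengths, field counts,
numeric fields, tag syntax, CIGAR/sequence agreement) and conservative
about content: SAM optional fields are kept as raw tab-joined text rather
than decoded triples, because re-encoding a float or array tag can change
its spelling and break byte-exact round trips.  The `+` line of FASTQ and
the SAM header are preserved verbatim.  Lossless configurations
reconstruct canonical LF input files byte-identically; this is asserted
end-to-end at 10 000 FASTQ and 50 000 SAM records.

Three adaptors implement the deliberate-loss and reference-coding paths:

* **Quality binning** maps every Phred+33 byte through the published
  Illumina RTA 8-level table (0–1→0, 2–9→6, 10–19→15, 20–24→22, 25–29→27,
  30–34→33, 35–39→37, ≥40→40).  The map is idempotent, its image over the
  working Phred range 0–41 has exactly 8 values, and a SAM `"*"`
  (quality absent) passes through untouched.  No inverse exists; binned
  files round-trip losslessly *thereafter*.
* **"Max" stripping** blanks the fields that dominate lossless size but
  carry no analysis signal: SAM read names become `"*"` and optional
  fields are dropped; FASTQ titles are replaced by the record's running
  ordinal (renumbering rather than blanking keeps records addressable).
* **Reference-based sequence coding** stores a mapped read as differences
  against the reference window addressed by `(rname, pos, cigar)`: one op
  per mismatching base in `M/=/X` segments, one op per `I`/`S` segment's
  bases; `D/N` consume reference only.  Records that cannot be addressed
  (unmapped, `*` CIGAR, contig absent) fall back to a verbatim branch of
  a union type, so encoding is total and never lossy; a CIGAR that
  disagrees with the sequence length or overruns the contig is an error,
  not a fallback.  Decoding is the declared inverse and runs as a
  post-adaptor at decompression.  Exactness is asserted over 20 000
  generated reads with substitutions, indels and soft-clips.

## Synthetic data

All tests run on generated inputs; nothing is downloaded.  The generators
are pure functions of a `generatorConfig()` and draw exclusively from a
splitmix64 generator compiled into the package, so fixtures are
bit-identical across platforms and R versions — R's own RNG never touches
them.  Defaults describe a small but representative resequencing
experiment: 2 contigs of 100 kb uniform ACGT, 100 bp reads, 0.5 %
per-base substitutions, a 2 % chance of one 1–4 bp indel per read, 5 %
leading soft-clips, 2 % unmapped records, coordinate-sorted output,
qualities uniform on Phred 0–41 (so all 42 symbols occur and binning is
observable).  Generated CIGAR and sequence are consistent by
construction, and every mapped read reference-decodes exactly, which ties
the generator to the reference-codec tests.

What the generator does *not* emulate — quality-dependent error spectra,
GC bias, mate pairs, real read-name structure — bounds what green tests
mean: they demonstrate correctness (round trips, query equivalence,
integrity, determinism), not the compression ratios of real data, which
depend on redundancy structure the simulator does not reproduce.

Problem sizes in the acceptance suite (10k/50k/100k/20k records) were
chosen as the smallest sizes at which chunking, multi-block streams,
multi-chunk queries and all adaptor paths are genuinely exercised.

## Numerical and degenerate-input choices

* Empty inputs are first-class: a 0-record file stores a descriptor with
  empty streams and round-trips to an empty file; `allocate(0)` is an
  empty block list; an empty container shrinks to zero blocks.
* Compressing an empty payload still emits the codec's empty
  representation (a few bytes), so chunk indexes never have holes.
* Key comparison is lexicographic over mixed numeric/byte-string tuples;
  string components compare bytewise, never through locale collation.
* Ties between equal keys never reorder records: chunks are committed in
  input order and queries filter in stored order.
* Out-of-range values (e.g. 256 in a `u8` field) are reported with the
  record ordinal and field path at serialization time, before anything is
  written.
* The `lzma` level is the xz preset; level ranges are validated at
  compress *and* decompress time so a corrupted catalog fails loudly.

## Known limitations

* Containers cannot grow; size generously and shrink.
* One writer per container (advisory lock); no crash *recovery* beyond
  the reserved-block garbage contract.
* Corruption is detected and attributed, never repaired.
* `u64`/`i64` are exact only to 2^53 in magnitude.
* No BAM/CRAM binary I/O, no mate-aware modeling, no 2-bit DNA packing —
  the latter is a natural codec plug-in rather than a wire-format change.
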