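Package: genarc
Title: Schema-Driven Columnar Compressed Storage for Genomic Record Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A format-free compressed-storage system for collections of
    genomic records. A record-type definition written in a small
    meta-language is turned into a set of independently compressed column
    streams (values, lengths and union tags) stored inside a block-allocated
    multi-dataset container file with per-block CRC32 checksums, verify and
    shrink operations. Datasets stored sorted by a user-defined key support
    range queries by bisection over sampled keys. Stock FASTQ and SAM
    compressors are built on the engine, including lossy adaptors
    (Illumina-style 8-level quality binning, read-name/optional-field
    stripping) and reference-based read-sequence encoding against a FASTA
    reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    jsonlite,
    parallel,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: zlib, bzip2, liblzma
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'wire.R'
    'codecs.R'
    'schema-parse.R'
    'schema-render.R'
    'schema-resolve.R'
    'streams-plan.R'
    'streams-serialize.R'
    'container.R'
    'engine.R'
    'fastq.R'
    'sam.R'
    'adaptors.R'
    'refcode.R'
    'fixtures.R'
    'cli.R'
    'zzz.R'
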