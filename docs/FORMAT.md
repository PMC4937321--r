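# Container and schema file formats

## Schema meta-language (`.garc`)

UTF-8 text. `#` starts a comment to end of line; whitespace is
insignificant.

```
document   := { definition }            # exactly one @record definition
definition := name "=" type ";"
            | "@record" name "{" { field } "}" [";"]
field      := name ":" type [ "@" method [ "(" level ")" ] ] ";"
type       := base { "[" [ integer ] "]" }
base       := primitive | name | "{" { field } "}"
            | "union" "{" field field { field } "}"
primitive  := u8|u16|u32|u64|i32|i64|char|flag|string|dna|qual
name       := [A-Za-z_][A-Za-z0-9_]*
```

* Array suffixes apply left to right: `u32[3][]` is a variable-length
  array of fixed `u32` triples.
* Named definitions are ordered and may reference earlier definitions
  only; self-reference is a cycle error.
* `dna` and `qual` are semantically distinct byte-string types sharing the
  `string` wire encoding; they drive type-aware adaptors and codec
  defaults.
* A field with no `@method` annotation inherits the nearest enclosing
  annotation, falling back to gzip level 6.

## Stream decomposition

| schema construct                | streams                                            |
|---------------------------------|----------------------------------------------------|
| fixed-width primitive field `f` | `f` (values, little-endian at declared width)      |
| `string`/`dna`/`qual` field `f` | `f.len` (u32 lengths) + `f.values` (byte payload)  |
| fixed array                     | element streams at the same path                   |
| variable array of fixed prims   | `f.len` + `f.values`                               |
| variable array of anything else | `f.len` + element streams under `f.item`           |
| nested record                   | recursion with dotted prefix                       |
| union `u`                       | `u.tag` (u8, 0-based) + streams under `u.<alt>`    |

Union branches not taken contribute zero bytes to their streams.  Chunks
(the unit of compression, parallelism and key sampling) always end on
record boundaries.

## Container files

A container is three files sharing a path prefix.

### `<prefix>.genarc-data` — block data area

Pre-sized at creation to `nBig*bigBlockSize + nSmall*smallBlockSize`
bytes.  Block slots are laid out big blocks first; block id `b` starts at
`b*bigBlockSize` for `b < nBig`, else
`nBig*bigBlockSize + (b-nBig)*smallBlockSize`.

Each slot: payload bytes from offset 0, then the trailer in the slot's
**last 8 bytes**: `payload_len` (u32 LE) and `crc32` of the payload
(u32 LE, zlib polynomial).  Payload capacity is therefore
`blockSize - 8`.  A stream fills its block list in order, every block to
capacity except the last.

### `<prefix>.genarc-meta` — settings + allocation table (fixed layout)

| offset | size | content                                         |
|--------|------|-------------------------------------------------|
| 0      | 8    | magic `"GENARC01"`                              |
| 8      | 2    | format version, u16 LE (currently 1)            |
| 10     | 32   | bigBlockSize, smallBlockSize, nBig, nSmall (u64 LE each) |
| 42     | nBig+nSmall | one state byte per block: 0 free, 1 reserved, 2 occupied |

### `<prefix>.genarc-ds` — dataset catalog (versioned JSON)

One object per dataset: `name`, canonical `schema` text, verbatim
`header` text, `n_records`, `chunk_records`, per-stream entries
(`path`, `method`, `level`, ordered `blocks` id list, `total_bytes`,
`chunks` as `[offset, compressed_len, uncompressed_len]` triples), and
`key_samples` (first key of every chunk; `null` for unsorted datasets).

A dataset is visible in the catalog only after all its blocks are
occupied; reserved-but-uncataloged blocks are reclaimable garbage.

### Locking

Writers hold an advisory lock file `<prefix>.genarc-lock` from their
first mutating operation until the handle is closed; one writer at a
time, any number of readers of finalized datasets.

## Codec plug-ins

A codec is two pure byte-to-byte functions plus a level range:

```r
registerCodec("ppmd",
              compress   = function(data, level) ...,   # raw -> raw
              decompress = function(data, sizeHint) ..., # raw -> raw
              levelRange = c(1, 16))
```

`decompress(compress(x, l), h) == x` must hold for every raw vector `x`,
every level and any size hint, and `compress` must be deterministic.
Compressed blocks carry no self-describing header — the method and level
live in the catalog — so changing a codec's output format is a container
format change.
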