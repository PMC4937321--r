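# Reference-based SAM record: the sequence field is a union of a verbatim
# byte string (unmapped / unaddressable reads) and a list of differences
# against the reference window addressed by (rname, pos, cigar).
DiffOp = {
  off: u32;     # 0-based query offset
  kind: u8;     # 0 = mismatch (single base), 1 = insert (segment bases)
  bases: dna;
};
@record Alignment {
  qname: string @gzip(6);
  flag: u16 @gzip(6);
  rname: string @gzip(6);
  pos: u32 @gzip(6);
  mapq: u8 @gzip(6);
  cigar: string @gzip(6);
  rnext: string @gzip(6);
  pnext: u32 @gzip(6);
  tlen: i64 @gzip(6);
  seq: union {
    verbatim: dna @bzip2(9);
    diffs: DiffOp[] @gzip(6);
  };
  qual: qual @bzip2(9);
  tags: string @gzip(6);
}
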