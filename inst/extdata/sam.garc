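# Stock lossless SAM record: one stream (pair) per mandatory field, plus a
# single raw-text stream holding the tab-joined optional fields verbatim.
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
  seq: dna @bzip2(9);
  qual: qual @bzip2(9);
  tags: string @gzip(6);
}
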