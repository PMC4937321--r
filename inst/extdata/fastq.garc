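# Stock FASTQ record: four variable-length byte-string fields.
# Read names compress well under gzip; bases and qualities are better
# served by bzip2's block-sorting transform.
@record Fastq {
  title: string @gzip(6);
  seq: dna @bzip2(9);
  plus: string @gzip(6);
  qual: qual @bzip2(9);
}
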