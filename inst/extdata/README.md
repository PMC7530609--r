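# Bundled example data

- `male_specific_repeats_synthetic.fasta` — **synthetic** male-specific
  repeat library generated with a fixed seed. It is not the deposited
  library from any sequencing experiment; it is constructed to carry the
  summary statistics such a library is expected to have (101 sequences,
  13,700 bp total, median length 101 bp) so the FASTA summary operation can
  be exercised offline.
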