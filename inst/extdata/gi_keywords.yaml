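# Keyword vocabulary for genomic-island features.
# Case-insensitive substring matches against gene product annotations.
# Edit freely; load with read_keyword_vocabulary().
phage_keywords:
  - phage
  - prophage
  - capsid
  - tail
  - terminase
  - portal
  - baseplate
  - holin
  - lysin
  - virion
mobility_keywords:
  - integrase
  - transposase
  - recombinase
  - mobile element
  - conjugal
  - conjugative
tRNA_keywords:
  - trna
  - transfer rna
unknown_function_markers:
  - hypothetical protein
  - uncharacterized
  - unknown function
  - putative uncharacterized
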