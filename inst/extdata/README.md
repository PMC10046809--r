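# Shipped gene-block definitions

- `block_I_hoxa.tsv` — the 11 HOXA-cluster genes (mouse symbols) driving
  early neuromuscular/skeletal development.
- `block_II_developmental.tsv` — 12 developmental regulators of
  cardiovascular formation and overall metabolism (the `Gdf10` symbol is the
  whitespace-repaired form of a commonly mistyped `GDF 10`). `Cdx` and `Gsx`
  are family stems; resolve them with `expand_variants()` or edit the file
  to the concrete symbols of your annotation.
- `dna_repair_block_default.tsv` — a curated, editable default list of 56
  canonical mouse DNA-repair genes (base/nucleotide excision, mismatch,
  recombination, end joining, translesion synthesis, damage signalling).
  The original 56-gene repair block this analysis style derives from was
  published only by citation; results on the default list are therefore a
  reference analysis of a comparable block, not a reproduction of the
  original block's values.

All files are read with `read_gene_block(path, catalog)`.
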