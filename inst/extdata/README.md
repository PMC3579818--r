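# Reference tables (optional)

The published family tables that freeze the original census inputs are
distributed as spreadsheet supplements alongside the article and are not
redistributed with this package. The checks in
`tests/testthat/test-acceptance.R` that recompute the published summary
numbers look for TSV conversions of those tables in this directory and
report a failure when they are absent.

Expected files and columns (tab-separated, header row; coordinates 0-based
half-open):

- `mouse_census_reference.tsv` — `gene_id`, `gene_symbol`,
  `transcript_id`, `protein_id`, `sequence` (amino acids), `n_zf`
  (published finger count), `cluster_id` (published cluster label, 0 =
  singleton), `chrom`, `start`, `end`, `strand`.
- `human_census_reference.tsv` — `gene_id`, `gene_symbol`, `protein_id`,
  `sequence`, `n_zf`.
- `ncounter_reference_averaged.tsv` — `gene_id`, `class`
  (`target`/`housekeeping`/`control`), then one column of averaged
  normalized counts per cell type.
- `genebody_marks_reference.tsv` — `gene_id`, `mark` (e.g. `H3K4me3`,
  `H3K27me3`, `H3K9me3`, `KAP1`), one row per enriched region overlapping
  the gene's extended window.

All other fixtures used by the test suite are generated in code by the
`sim_*` generators.
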