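# File formats

## Fragments file

Tab-delimited, no header, one fragment per row, sorted by
(chrom, start, end, cell). Coordinates are 0-based, half-open (BED
convention).

| column | name         | notes                                   |
|--------|--------------|-----------------------------------------|
| 1      | chrom        | contig name                             |
| 2      | start        | 0-based, Tn5-centered                   |
| 3      | end          | half-open                               |
| 4      | cell_barcode | cell id                                 |
| 5      | read_count   | integer >= 1                            |
| 6      | r1_meta      | META tag id of mate 1                   |
| 7      | r2_meta      | META tag id of mate 2                   |
| 8      | allele       | M (maternal), P (paternal), I, U        |

Columns 1-5 match the common single-cell fragments format; columns 6-8
are appended so five-column readers remain compatible. Plain or gzip
(`.gz`) compression.

## Alignment-pair table

Tab-delimited with header, one properly paired alignment per row:
`read_id, chrom, r1_strand, r1_start, r1_end, r2_start, r2_end, mapq,
is_proper`. Coordinates 0-based half-open; `mapq` is the minimum of the
two mates.

## BED inputs (peaks, DHSs, TSSs)

Standard 3+ column BED; `track`/`browser`/`#` lines are skipped; column
6, when present, is the strand (used for TSSs).

## Pair-score table (BEDPE-like)

`chrom_i, start_i, end_i, chrom_j, start_j, end_j, N, M, n, x, score`
with a header row; coordinates 0-based half-open.

## Matrix export

MatrixMarket `<prefix>.mtx` (cells x peaks) with `<prefix>.cells.tsv`
(one cell id per line) and `<prefix>.peaks.tsv` (3-column BED of peaks).

## RNA read table

Tab-delimited with header: `cell_id, gene_id, umi, downstream_5bp` (the
5 bases 3' of the UMI), optionally `pattern_mismatches`.

## Run configuration

YAML key-value file; recognised keys: `scheme`, `min_mapq`,
`max_bc_mismatch`, `max_meta_mismatch`, `species_human_cutoff`,
`species_mouse_cutoff`, `xci_lower`, `xci_upper`, `xci_min_informative`,
`fdr_alpha`, `seed`, `output_dir`. Unknown keys are errors.
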