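# Toy-locus end-to-end configuration (paths relative to this file)
output_dir: pipeline_out
seed: 20260101
annotation:
  gtf: toy.gtf
  repeat_bed: repeats.bed
  repeat_body_name: repeat_body
  rules:
    ERVK7.long: {type: unique, target: ERVK7.long, against: [ERVK7.short, ERVK7.ltr]}
    ERVK7.short: {type: unique, target: ERVK7.short, against: [ERVK7.long, ERVK7.ltr]}
    ERVK7: {type: repeat_body}
counts:
  block_table: reads.tsv
junctions:
  region_a: LTR5Hs
  region_b: HERVK-int
  threshold: 1
  total_mapped: 1000000
decomposition:
  samples: samples.tsv
  epsilon: 0.01
methylation:
  bedmethyl: methylation.tsv
  chrom: toy1
  start: 2000
  end: 2968
consensus:
  msa: ltr_msa.fa
  query_id: ERVK7_5LTR
single_cell:
  cells: cells.tsv
  features: [ERVK7_long, ERVK7_short, ERVK7_gene]
  min_cells_per_type: 100
  type_set: [tumor, AT2, fibroblast]
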