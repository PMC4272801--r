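# Bundled toy pipeline configuration: a 100 kb single-chromosome genome with
# three TE families (one carrying a planted poly-U probe), 30 genes and 8,000
# CLIP-like reads. Small enough for an end-to-end run in about a minute.
simulation:
  seed: 303
  n_chroms: 1
  chrom_len: 100000
  n_genes: 30
  n_reads: 8000
  te_families:
    - name: AluY
      cons_length: 300
      n_copies: 40
      truncation_rate: 0.1
      substitution_rate: 0.05
    - name: L2
      cons_length: 500
      n_copies: 20
      truncation_rate: 0.3
      substitution_rate: 0.08
    - name: AluP
      cons_length: 300
      n_copies: 20
      truncation_rate: 0.0
      substitution_rate: 0.02
  planted_motifs:
    - motif: ACCGTTAGC
      family: AluP
      multiplier: 10
      n_nonrep: 15
params:
  min_reads: 5000
  top_n: 20
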