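# Pipeline configuration for a METABRIC-like microarray cohort.
# Expression arrives as per-gene cohort z-scores, where a geometric mean
# is undefined, so CYT falls back to the rank-based surrogate; the
# CYT-high fraction is cohort-specific at 8%.
inputs:
  expression: data/metabric/expression_zscores.tsv
  scale: zscore
  fractions: data/metabric/immune_fractions.tsv
  clinical: data/metabric/clinical.tsv
  features: data/metabric/sample_features.tsv
  gene_sets: data/metabric/hallmark.gmt
cd8_top_fraction: 0.85
cyt_top_fraction: 0.08     # microarray cohort: a far smaller CYT-high group
dge_pairs:
  - [CTI, HTI]
  - [NI, HTI]
  - [CTI, NI]
fc_threshold: 1.5
p_threshold: 0.05
gsea:
  n_perm: 1000
  seed: 17
  nes_threshold: 1.7
  q_threshold: 0.01
survival:
  endpoints: [bcss, rfs_distant, rfs_local]
  strata: subtype
output_dir: results/metabric_like
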