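# Pipeline configuration for a TCGA-like RNA-seq cohort.
# Expression arrives as RSEM estimated abundances and is converted to TPM
# before the geometric-mean CYT score; the CYT-high fraction is 40%.
inputs:
  expression: data/tcga/expression_rsem.tsv   # Hugo_Symbol + one column per sample
  scale: rsem
  fractions: data/tcga/immune_fractions.tsv   # 22 CIBERSORT cell types per sample
  clinical: data/tcga/clinical.tsv
  features: data/tcga/sample_features.tsv     # TMB, neoantigens, checkpoint genes
  gene_sets: data/tcga/hallmark.gmt
pseudocount: 0.01          # TPM offset inside the geometric mean
cd8_top_fraction: 0.85     # top 85% of CD8 fractions called CD8-high
cyt_top_fraction: 0.40     # top 40% of CYT called CYT-high (RNA-seq cohort)
dge_pairs:
  - [CTI, HTI]
  - [NI, HTI]
  - [CTI, NI]
fc_threshold: 1.5
p_threshold: 0.05
gsea:
  n_perm: 1000
  seed: 17                 # mandatory: the permutation null is stochastic
  nes_threshold: 1.7
  q_threshold: 0.01
survival:
  endpoints: [os, pfs]
  strata: subtype          # whole cohort plus HR+HER2- / HER2+ / TN
output_dir: results/tcga_like
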