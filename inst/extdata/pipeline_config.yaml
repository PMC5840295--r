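# Example pipeline configuration. Every stochastic stage uses `seed`.
seed: 1
out_dir: spectracall_out
stages:
  - simulate_apms
  - enrich
  - score
  - call
  - classify
  - export
  - simulate_rnaseq
  - de_filter
  - endogenous
  - concordance
  - phenotype
apms:
  n_proteins: 200
  n_interactors: 20
  enrichment_factor: 8
  dispersion: 0.005
criteria:
  min_fold: 2
  max_t_p: 0.05
  min_significant_runs: 2
  min_saint: 0.90
  g_alpha: 0.05
rnaseq:
  n_genes: 1000
  n_yfp: 20
  n_matr3: 10
  effect_log2: 1
  dispersion: 0.005
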