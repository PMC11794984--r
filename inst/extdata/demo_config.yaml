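# Demonstration pipeline configuration: a reduced-scale synthetic cohort that
# keeps the 31-sample / 11-8-12 group design but fewer probes and genes.
seed: 11
simulate:
  n_probes: 4000
  n_genes: 600
select:
  mode: fraction
  amount: 0.01
cluster:
  distance: euclidean
  linkage: ward.D2
  perplexity: 5
dm:
  delta_threshold: 0.2
  alpha: 0.05
de:
  alpha: 0.05
  lfc_threshold: 0
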