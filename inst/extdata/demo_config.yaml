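# Demo pipeline configuration: a desk-scale synthetic cohort that runs the
# whole chain (cfDNA selection screen -> signature -> outcomes -> PDX) in
# well under two minutes on one CPU.
seed: 20
log_level: quiet
cfdna:
  n_patients: 120
selection:
  threshold_points: 25
  min_selected: 2
  fdr_cutoff: 0.2
expression:
  n_samples: 120
  n_genes: 500
  n_up: 8
  n_down: 56
  effect_size: 2.0
signature:
  fdr_cutoff: 0.05
  include_msi: true
outcomes:
  interaction_hr: 3.3
pdx:
  n_models: 132
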