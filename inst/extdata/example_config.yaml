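# Example pipeline configuration. Paths are relative to the working
# directory of the run; generate the matching inputs with runSimulate().
reference:
  fasta: fixtures/references.fa
catalogue: fixtures/site_catalogue.tsv
design: fixtures/design.tsv
input:
  type: counts          # counts | sam
  dir: fixtures/counts
score:
  k: 6
  weight_scheme: linear_decay
  min_site_coverage: 100
  clamp: true
contrasts:
  - [ESC_WT, NSC_WT]
  - [NSC_WT, Neuron_WT]
trajectory: [ESC_WT, NSC_WT, Neuron_WT]
alpha: 0.05
hypo_threshold: 0.9
variability_delta: 0.05
out_dir: results
seed: 1
qpcr:
  rtlp: fixtures/qpcr_rtlp.tsv
  dilution: fixtures/qpcr_dilution.tsv
  top_standard_copies: 1.0e6
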