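# Shared configuration for the numbered analysis scripts (run from the
# repository root). Keys mirror conaccr::pipeline_config().
seed: 20240601
alpha: 0.05
use_gamma: false
flank_distance: 5000
ncrna_min_frac: 0.8
background_mode: exclusive
target_branches:
  - A_carolinensis
  - A_porcatus
  - A_allisoni
  - A_isolepis
  - A_sagrei
  - A_homolechis
  - A_allogus
  - TC_open
simulate:
  n_neutral: 600
  n_conserved: 200
  n_accelerated: 200
  region_length: 60
  conserved_scale: 0.1
  accelerated_scale: 10
  target_branch: A_sagrei
  ncrna_every: 10
  n_neutral_sites: 20000
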