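# End-to-end synthetic demonstration: simulate a small two-variety cohort on
# both instruments, process, quantify, score, fit and compare.
output_dir: demo_out
instruments:
  - name: high_field
    scheme: high_field
    windows: high_field
  - name: benchtop
    scheme: benchtop
    windows: benchtop
processing:
  zero_fill_to: 65536
  exponential_lb: 0.3
  phase_mode: auto
  baseline_mode: none
  reference_target: 5.22
weights:
  sucrose: 1.0
  fructose: 1.3
  glucose: 0.6
simulation:
  varieties:
    - variety_id: demoA
      target_ratio: 9.0
    - variety_id: demoB
      target_ratio: 5.0
    - variety_id: demoC
      target_ratio: 7.0
  n_replicates: 3
  replicate_cv: 0.08
  seed: 20220809
  acceptability_rule:
    slope: 0.6
    intercept: 1.0
    noise_sd: 0.25
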