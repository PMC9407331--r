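# Fit both acceptability models from the bundled reference variety table
# (no simulation stage).
output_dir: table1_out
acceptability_table: table1
weights:
  sucrose: 1.0
  fructose: 1.3
  glucose: 0.6
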