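# Example run configuration: one file drives one reproducible run.
model: benthic
scenario:
  preset: warm
  ppO2: 30
seed: 1
verbosity: 1
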