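# Example rate-table override. Any omitted block falls back to the
# package defaults (see ?read_rate_table). Values below illustrate the
# schema; replace them with your own calibration.
calcification:
  acropora_palmata: 10.88
  pseudodiploria: 9.84
  cca: 2.09
rugosity:
  acropora_palmata: 3.3309
  pseudodiploria: 1.79
density:
  acropora_palmata: 1450
  pseudodiploria: 1600
urchin:
  a: 0.0045
  b: 3
  reingestion: 0.57
core:
  sed: 33
  void: 18
  frame: 49
substrate_categories: [dead_coral]
parrotfish:
  - {species: sparisoma_viride, size_bin: 150, phase: initial, rate: 28941}
  - {species: sparisoma_viride, size_bin: 150, phase: terminal, rate: 43412}
  - {species: sparisoma_viride, size_bin: 225, phase: initial, rate: 93096}
  - {species: sparisoma_viride, size_bin: 225, phase: terminal, rate: 139644}
  - {species: scarus_vetula, size_bin: 150, phase: initial, rate: 13023}
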