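# Example run configuration: healthy baseline at reduced lattice size.
scenario: healthy
seed: 1
days: 18
lattice: [100, 100]
replicates: 3
overrides:
  rules:
    PSNC: 0.15
    TSEN: 12
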