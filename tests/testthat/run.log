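xlinkfit 0.9.0
subcommand: fit
config hash: 44905551
seed: NA
R: R version 4.3.3 (2024-02-29)
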