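# Demo configuration for the synthetic claims generator.
n_members: 5000
n_months: 30
treatment_effect_pupm: -10
seed: 1
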