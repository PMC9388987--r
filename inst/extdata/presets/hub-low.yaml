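site: hub
level: low
reps: 20
seed: 1
no_show_prob: 0.02
adverse_prob: 0.02
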