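# Sex is an instrumental variable: men cannot be exposed but sex has no
# direct effect on the outcome (risk ratio 1).
label: instrument
rr_A_on_Y: 1.3
rr_C_on_A: 1.75
rr_C_on_Y: 1.75
rr_sex_on_Y: 1.0
p_female: 0.5
p_C: 0.5
p_Y_baseline: 0.10
target_exposure_prev: 0.69
"n": 10000
iterations: 1000
seed: 1
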