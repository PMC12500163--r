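model: pow_additive_cis
pA: 0.2
pB: 0.2
dprime: 0.0
n_cases: 80.0
n_controls: 80.0
n_iter: 4.0
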