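# Standard two-site nest-choice configuration: colony of 100 ants, 20%
# high-threshold, 30% scouts, symmetric conversion rates, quorum at half the
# colony. Keys mirror the nest_params() arguments; a `preset` key may name a
# built-in parameter set which the remaining keys then override.
preset: baseline
H: 0.2
z: 0.3
alpha: 0.1
alpha_s: 0.1
alpha_leak: 0.05
N: 100
quorum_fraction: 0.5
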