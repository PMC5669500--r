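# phagosim run configuration: intermediate-binding production scenario.
# Any omitted key falls back to the package default; unknown keys are
# rejected. The scenario preset supplies kappa = 10, K_A = 2e5, K_V = 5e5
# and u = 0.12; explicit keys below override preset values.
scenario: fused3_s6
n_sweeps: 10000
stride: 100
seed: 7
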