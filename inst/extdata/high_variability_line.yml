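# High-ABA-sensitivity ("high variability") parameterization: only the ABA
# threshold for Integrator production differs from the package defaults.
theta_I_ABA: 5.8
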