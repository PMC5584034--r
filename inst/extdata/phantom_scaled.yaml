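# Moving-sphere phantom experiment, scaled preset: both sphere speeds,
# all four reconstructions, widths of phase 5 of 9.
experiment: phantom
scale: scaled
speeds: [60s, 30s]
methods: [fdk, tvcs, piccs, tcgm]
n_phases: 9
tvcs_window: 200
refine_window: 90
eval_phase: 5
seed: 1
output_dir: results/phantom_scaled
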