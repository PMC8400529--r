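# Example annulight run configuration: a reduced grid in the coarse
# spectral mode. Unset keys fall back to the full-grid defaults.
classes: [clear, moderate, turbid]
zenith: [0, 30, 60]
cloud: [0.0, 0.4, 1.0]
spectral_res: 10
noise_sd: 0.0
depth_ranges: [0.5, 1.5]
ratio_depths: [1.5]
verbosity: 1
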