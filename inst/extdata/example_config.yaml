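# Example configuration for the CLI `simulate` command (synthetic scenes):
#   Rscript inst/cli/icgfa.R simulate --config example_config.yaml --seed 1 --out out/
n_scenes: 3
n_poor: 1
fps: 2
duration: 45
frame_height: 120
frame_width: 300
noise_sd: 5
motion_amplitude: 2
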