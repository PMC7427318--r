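# Example pipeline configuration (fields mirror session_config()).
n_units: 4
n_directions: 12
n_repeats: 8
duration: 700
coupling: 0.6
gain_ratio: 0.7
noise_sd: 0.1
n_axons: 2
seed: 1
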