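# Example region configuration for `dasycan.R run --config ...`
# Keys mirror region_config(); omitted keys keep their defaults.
n_units: 100
grid_rows: 90
grid_cols: 90
frac_mountain_units: 0.5
n_vet_practices: 40
dog_per_100_humans: 6.54
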