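# Example run configuration for the allometherm pipeline.
# Stage products are written under out_dir; one seed reproduces the run.
out_dir: allometherm_run
seed: 1
r2_threshold: 0.96
min_duration: 180
n_boot: 100
ci_limit_c: 1.5
ref_mass: 0.065
study:
  n_fish: 12          # scaled-down demonstration cohort
  n_cardiac: 6
  mass_range: [0.005, 0.700]
  temperatures: [12, 16, 20, 22]
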