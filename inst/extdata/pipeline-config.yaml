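# Example chronosleep pipeline configuration.
# Any field omitted here falls back to default_pipeline_config().
#
#   Rscript -e 'chronosleep::run_pipeline("pipeline-config.yaml", "run1")'
# or, via the wrapper installed under inst/scripts:
#   chronosleep run --config pipeline-config.yaml --out run1

seed: 1                    # master seed; all stage randomness derives from it
groups: [WT, MUT]          # group labels; must index the per-group sim fields

sim:                       # passed to sim_config(); see ?sim_config
  n_animals_per_group: 4
  recording_days: 1        # use 2 (baseline + SD day) with sleep_deprivation
  artifact_probability: 0.02
  # diurnal_modulation_depth: {WT: 0.4, MUT: 0.15}
  # theta_center_frequency:  {WT: 7.2, MUT: 7.6}

sleep_deprivation: false   # force WAKE in sd_window on day 2
wheel_days: 2              # days of wheel recording (0 disables)
bin_hours: 2               # vigilance time-course bin width
wheel_bin_minutes: 18      # activity-profile bin width

spectral:                  # only used when the "spectral" stage is requested
  tpf_interval: [0, 12]    # recording hours for the REM mean spectrum
  reference_epochs: 900    # SWA baseline window length
  min_nrem_epochs: 10      # minimum NREM epochs per SWA bin

network:                   # graph/terms default to the bundled synthetic files
  extra_seeds: [BHLHE41, BHLHE40]
  # graph: /path/to/edges.tsv   (columns: from, to[, type])
  # terms: /path/to/sets.gmt
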