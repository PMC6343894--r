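# Template configuration for the hydrollp pipeline. Every entry here
# mirrors a default of hydrollp::default_config(); a user file needs to
# state only what it overrides.

design:
  treatments: [R0HP, R1HP, R1BF, R2HP, R2BF]
  replicates: 5
  school_size: 5
  event_duration: 2400     # s (40-minute flow event)
  acclimation: 1800        # s

flow:
  peak_discharge: 60       # l/s
  base_discharge: 7        # l/s
  up_ramp_duration: 28.12  # s
  depth_increase: 15.7     # cm

grid:
  n_rows: 15               # streamwise; row 1 most upstream
  n_cols: 3                # lateral; col 1 left wall looking downstream
  flume_width: 0.7         # m
  reach_length: 6.5        # m
  wake_length: 3           # cells behind each structure

trace:
  base_velocity: 0.1       # m/s under base flow
  base_depth: 0.1          # m
  sampling_rate: 200       # Hz
  duration: 60             # s per grid cell
  turbulence_floor: 1      # Pa
  turbulence_coef: 0.12    # Pa per Pa of dynamic pressure
  wake_velocity_factor: 0.3
  side_velocity_factor: 1.3
  background_vortex: 1     # Pa
  wake_vortex_base: 8      # Pa
  wake_vortex_coef: 0.05
  vortex_scale:
    R1: 1.0
    R2: 1.6
  strouhal: 0.2

asymmetry_mode: pairmean   # pairmean | timemean | literal
n_permutations: 999
rounding:
  stats: 3
  pressure: 2
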