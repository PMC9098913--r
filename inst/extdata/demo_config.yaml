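# All-synthetic demonstration pipeline: simulate two-state tracks, call
# confinement events, estimate a photobleach-corrected lifetime, and fit a
# binding curve. Units: um, s, uM.
seed: 7
output_dir: demo_output
stages:
  - name: simulate_tracks
    n_molecules: 30
    n_frames: 200
  - name: confine
    p_thresh: 1000
    t_thresh: 0.25
  - name: dwell_lifetime
    n_molecules_per_interval: 1000
  - name: packing
    footprint_nm2: 30
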