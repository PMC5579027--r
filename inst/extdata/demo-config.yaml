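# Demo configuration: a short recording of 10 um beads in a straight
# 150 x 30 um (h = 20 um) channel with both measurement streams.
geometry:
  kind: straight
  length_um: 150
  width_um: 30
  height_um: 20
  resistivity_ohm_m: 0.095
simulate:
  n_particles: 6
  duration_s: 0.15
  d_um: 10
  v_max_um_s: 1.0e+5
  alpha: 6
  ell_t_um: 15
  access_frac: 0.5
acquisition:
  sample_period_s: 4.0e-6
  frame_period_s: 2.0e-5
  exposure_s: 5.0e-6
  baseline_current_A: 5.0e-8
  noise_sd_A: 2.0e-11
detect_rp:
  k: 6
  lowpass_hz: 1.0e+4
sync:
  tol: 2.0e-3
analyze:
  map_bin_um: 1
  profile_window_um: 1
seed: 7
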