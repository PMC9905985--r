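config_version: 1
geometry:
  segment_lengths:
  - 0.3
  - 0.25
  - 0.18
  segment_masses:
  - 2.0
  - 1.2
  - 0.5
  segment_com_offsets:
  - 0.135
  - 0.1125
  - 0.09
  segment_inertias:
  - 0.015
  - 0.00625
  - 0.00135
  joint_min:
  - -0.174532925199433
  - 0.0
  - -0.785398163397448
  joint_max:
  - 2.617993877991494
  - 2.617993877991494
  - 0.785398163397448
  initial_joint_angles:
  - 1.221730476396031
  - 1.308996938995747
  - 0.0
  chest_span: 0.44
  limit_stiffness: 500.0
  limit_damping: 5.0
muscles:
  fmax:
  - 800.0
  - 800.0
  - 600.0
  - 600.0
  - 200.0
  - 200.0
  l0:
  - 0.15
  - 0.15
  - 0.13
  - 0.13
  - 0.06
  - 0.06
  moment_arm:
  - 0.026857396646757
  - 0.026857396646757
  - 0.024828171122336
  - 0.024828171122336
  - 0.019098593171027
  - 0.019098593171027
  sign:
  - 1
  - -1
  - 1
  - -1
  - 1
  - -1
  joint:
  - 1
  - 1
  - 2
  - 2
  - 3
  - 3
  fl_width: 0.45
  v_max: 10.0
  fv_curvature: 0.25
  fv_flen: 1.5
  act_tau:
  - 0.015
  - 0.015
  - 0.015
scenarios:
- label: no_passive
  s_p: 0.05
  r_p: 5.0
  l_p: 1.3
- label: A
  s_p: 0.05
  r_p: 5.0
  l_p: 1.1
- label: B
  s_p: 0.075
  r_p: 5.0
  l_p: 1.1
- label: C
  s_p: 0.05
  r_p: 8.0
  l_p: 1.1
- label: D
  s_p: 0.075
  r_p: 8.0
  l_p: 1.1
- label: E
  s_p: 0.05
  r_p: 5.0
  l_p: 1.0
- label: F
  s_p: 0.075
  r_p: 5.0
  l_p: 1.0
- label: G
  s_p: 0.05
  r_p: 8.0
  l_p: 1.0
- label: H
  s_p: 0.075
  r_p: 8.0
  l_p: 1.0
settings:
  dt: 0.001
  n_sub: 4
  homing: 1.0
  v_avg: 0.5
  t_min: 0.4
  k_ik: 20.0
  ik_damping: 0.02
  k_ns: 2.0
ga:
  population: 40
  generations: 60
  kp_max: 300.0
  kd_max: 50.0
  t_pred_max: 0.1
  elites: 2
  tournament: 3
  p_mut_real: 0.25
  p_mut_int: 0.3
  mut_sd: 0.1
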