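name: fanger-warmwall
dt: 1.0
cadence: 60.0
method: rk4
seed: 1
clothing:
- segment: chest
  i_cl: 0.093
  r_ecl: 0.015
- segment: abdomen
  i_cl: 0.093
  r_ecl: 0.015
- segment: upper_arm_l
  i_cl: 0.093
  r_ecl: 0.015
- segment: upper_arm_r
  i_cl: 0.093
  r_ecl: 0.015
- segment: forearm_l
  i_cl: 0.093
  r_ecl: 0.015
- segment: forearm_r
  i_cl: 0.093
  r_ecl: 0.015
- segment: thigh_l
  i_cl: 0.093
  r_ecl: 0.015
- segment: thigh_r
  i_cl: 0.093
  r_ecl: 0.015
- segment: calf_l
  i_cl: 0.093
  r_ecl: 0.015
- segment: calf_r
  i_cl: 0.093
  r_ecl: 0.015
- segment: foot_l
  i_cl: 0.093
  r_ecl: 0.015
- segment: foot_r
  i_cl: 0.093
  r_ecl: 0.015
stages:
- duration: 3600.0
  t_air: 23.0
  p_air: 1.400036040146
  t_mrt: 23.0
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
  panels:
  - t_r: 23.0
    width: 2.5
    height: 2.5
    distance: 0.5
    z0: 0.0
    x_offset: 0.0
    targets:
    - segment: head
      sector: exterior
    - segment: chest
      sector: exterior
    - segment: abdomen
      sector: exterior
    - segment: upper_arm_l
      sector: exterior
    - segment: forearm_l
      sector: exterior
    - segment: hand_l
      sector: exterior
    - segment: thigh_l
      sector: exterior
    - segment: calf_l
      sector: exterior
    - segment: foot_l
      sector: exterior
- duration: 1800.0
  t_air: 21.9
  p_air: 1.400036040146
  t_mrt: 21.9
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
  panels:
  - t_r: 32.6
    width: 2.5
    height: 2.5
    distance: 0.5
    z0: 0.0
    x_offset: 0.0
    targets:
    - segment: head
      sector: exterior
    - segment: chest
      sector: exterior
    - segment: abdomen
      sector: exterior
    - segment: upper_arm_l
      sector: exterior
    - segment: forearm_l
      sector: exterior
    - segment: hand_l
      sector: exterior
    - segment: thigh_l
      sector: exterior
    - segment: calf_l
      sector: exterior
    - segment: foot_l
      sector: exterior
- duration: 1800.0
  t_air: 20.7
  p_air: 1.400036040146
  t_mrt: 20.7
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
  panels:
  - t_r: 42.0
    width: 2.5
    height: 2.5
    distance: 0.5
    z0: 0.0
    x_offset: 0.0
    targets:
    - segment: head
      sector: exterior
    - segment: chest
      sector: exterior
    - segment: abdomen
      sector: exterior
    - segment: upper_arm_l
      sector: exterior
    - segment: forearm_l
      sector: exterior
    - segment: hand_l
      sector: exterior
    - segment: thigh_l
      sector: exterior
    - segment: calf_l
      sector: exterior
    - segment: foot_l
      sector: exterior
- duration: 1800.0
  t_air: 19.3
  p_air: 1.400036040146
  t_mrt: 19.3
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
  panels:
  - t_r: 51.6
    width: 2.5
    height: 2.5
    distance: 0.5
    z0: 0.0
    x_offset: 0.0
    targets:
    - segment: head
      sector: exterior
    - segment: chest
      sector: exterior
    - segment: abdomen
      sector: exterior
    - segment: upper_arm_l
      sector: exterior
    - segment: forearm_l
      sector: exterior
    - segment: hand_l
      sector: exterior
    - segment: thigh_l
      sector: exterior
    - segment: calf_l
      sector: exterior
    - segment: foot_l
      sector: exterior
- duration: 1800.0
  t_air: 17.9
  p_air: 1.400036040146
  t_mrt: 17.9
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
  panels:
  - t_r: 61.1
    width: 2.5
    height: 2.5
    distance: 0.5
    z0: 0.0
    x_offset: 0.0
    targets:
    - segment: head
      sector: exterior
    - segment: chest
      sector: exterior
    - segment: abdomen
      sector: exterior
    - segment: upper_arm_l
      sector: exterior
    - segment: forearm_l
      sector: exterior
    - segment: hand_l
      sector: exterior
    - segment: thigh_l
      sector: exterior
    - segment: calf_l
      sector: exterior
    - segment: foot_l
      sector: exterior
- duration: 1800.0
  t_air: 16.7
  p_air: 1.400036040146
  t_mrt: 16.7
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
  panels:
  - t_r: 70.1
    width: 2.5
    height: 2.5
    distance: 0.5
    z0: 0.0
    x_offset: 0.0
    targets:
    - segment: head
      sector: exterior
    - segment: chest
      sector: exterior
    - segment: abdomen
      sector: exterior
    - segment: upper_arm_l
      sector: exterior
    - segment: forearm_l
      sector: exterior
    - segment: hand_l
      sector: exterior
    - segment: thigh_l
      sector: exterior
    - segment: calf_l
      sector: exterior
    - segment: foot_l
      sector: exterior
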