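name: uniform-fourstage
dt: 1.0
cadence: 60.0
method: rk4
seed: 1
clothing:
- segment: abdomen
  i_cl: 0.016
  r_ecl: 0.003
- segment: thigh_l
  i_cl: 0.016
  r_ecl: 0.003
- segment: thigh_r
  i_cl: 0.016
  r_ecl: 0.003
stages:
- duration: 1800.0
  t_air: 29.0
  p_air: 1.997314921745
  t_mrt: 29.0
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
- duration: 1800.0
  t_air: 45.0
  p_air: 2.867940777777
  t_mrt: 45.0
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
- duration: 1800.0
  t_air: 29.0
  p_air: 1.997314921745
  t_mrt: 29.0
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
- duration: 1800.0
  t_air: 45.0
  p_air: 2.867940777777
  t_mrt: 45.0
  h_c: 3.0
  h_r: 4.7
  h_e: 49.5
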