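b0: 707.445
b0_stationary: 235.815
d: 0.005
r: 0.01
sigma: 100.0
C0: 0.4
C0_starvation: 0.04
m_min: 0.0001
m_max: 0.1
T: 0.85
T_high: 1.0
theta_nat: 0.6
G_ref: .na.real
calibrate_b0: yes
cap: 5000.0
n_seed: 500.0
t_max: 30000
t_apply: 20000
n_struct: 10000.0
seed: 1.0
protocol: starvation
C_init: ~
record_every: 1
log_divisions: no
k_form: centered
design:
  p_nat_threshold: 0.85
  p_int_threshold: 0.8
  max_steps: 30000.0
constant_b: ~
stress_new_value: ~
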