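# Final population pharmacokinetic model of treosulfan (pediatric, IV
# infusion).  Typical values are referenced to a 70-kg individual; omega are
# log-scale IIV standard deviations; corr_cl_v1 is the correlation between
# the clearance and central-volume random effects; residual error is purely
# proportional.  Units: L, L/h, mg/L, h.
theta:
  cl: 14.7
  v1: 26.0
  q: 2.25
  v2: 9.93
beta:
  cl: 0.75
  v1: 1.0
  q: 0.0
  v2: 1.0
ref_weight: 70
omega:
  cl: 0.255
  v1: 0.514
  q: 0.386
corr_cl_v1: 0.714
prop_error_b: 0.188
add_error: 0
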