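# Synthetic stand-in coefficient configuration for the PUL risk models.
#
# The coefficient vectors below are NOT the published M4/M6 coefficients:
# they were estimated once, by multinomial logistic regression, on large
# simulated development cohorts (M6P/M6NP on the package's default cohort
# profile; M4 on a deliberately shifted profile with a simpler basis, so
# that it transports worse, as an older model would). They share the
# published models' structure and operating points and exist so that the
# validation pipeline can be exercised end to end.
# The Step-1 risk triple, thresholds and ratio band are the published
# operating points.
provenance: synthetic (estimated on simulated development cohorts)
units:
  hcg: IU/l
  progesterone: nmol/l
step1:
  progesterone_cutoff: 2
  risks: {fpul: 0.961, iup: 0.022, ep: 0.017}
thresholds:
  ep_high_risk: 0.05
ratio_cutoffs:
  lower: 0.87
  upper: 1.66
models:
  M4:
    reference: FPUL
    basis: [intercept, log_hcg0, log_ratio]
    beta_iup: [-2.467591, 0.129707, 5.912215]
    beta_ep: [-1.939338, 0.087104, 2.057667]
  M6P:
    reference: FPUL
    basis: [intercept, log_hcg0, log_ratio, sq_log_ratio, log_prog0]
    beta_iup: [-9.215690, -0.202504, 11.582052, -4.165758, 2.978053]
    beta_ep: [-2.482367, -0.082581, 2.698944, -0.611220, 1.206866]
  M6NP:
    reference: FPUL
    basis: [intercept, log_hcg0, log_ratio, sq_log_ratio]
    beta_iup: [-2.875867, 0.138910, 11.223934, -3.598236]
    beta_ep: [-0.954005, 0.096745, 2.791583, -0.395043]

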