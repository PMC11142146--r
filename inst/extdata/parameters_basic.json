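{
  "_units": "time: days; volume: ml; amounts: pmol; concentrations: nM (pmol/ml); cell counts: units of 1e7 cells",
  "lambda_decay": 0.07,
  "k_on": 11.15,
  "kappa_c": 0.1,
  "kappa_p": 1,
  "gamma": 2.1,
  "V": 1,
  "nu": 0.015,
  "k_s": 0.3,
  "rho": 0.34,
  "omega": 0.05,
  "alpha": 500,
  "k_f": 0.05,
  "eta": 1780,
  "N0": 3,
  "N_cur": 1e-9,
  "C_d": 1e4,
  "A_bl_cr": 0.0175
}
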