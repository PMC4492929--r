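{
  "subset": "all",
  "w0": 1.81729,
  "weights": {
    "d_ie": 0.06648,
    "dd_ee": 0.39117,
    "dd_ve": 0.18732,
    "dd_sp": 0.43118,
    "dd_sn": 0,
    "dd_s": 0.20841,
    "dd_hydr": -0.6731,
    "d_hb": 0,
    "interface_mt": 4.64209e-04,
    "dd_sasa_over_interface": 9.82407
  },
  "pvalues": {
    "w0": 0,
    "d_ie": 0,
    "dd_ee": 0,
    "dd_ve": 0,
    "dd_sp": 0,
    "dd_s": 2.0e-04,
    "dd_hydr": 1.48e-10,
    "interface_mt": 3.64e-10,
    "dd_sasa_over_interface": 1.18e-05
  }
}
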