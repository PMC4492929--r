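{
  "subset": "small",
  "w0": 0.74345,
  "weights": {
    "d_ie": 0.03538,
    "dd_ee": 0.24695,
    "dd_ve": 0.1405,
    "dd_sp": 0.26,
    "dd_sn": 0.00354,
    "dd_s": 0.17197,
    "dd_hydr": 0,
    "d_hb": 0,
    "interface_mt": 1.67e-04,
    "dd_sasa_over_interface": 7.75803
  },
  "pvalues": {
    "w0": 2.61e-06,
    "d_ie": 1.57e-06,
    "dd_ee": 1.83e-07,
    "dd_ve": 8.99e-06,
    "dd_sp": 2.77e-06,
    "dd_sn": 2.90e-02,
    "dd_s": 9.80e-02,
    "interface_mt": 1.22e-02,
    "dd_sasa_over_interface": 2.79e-03
  },
  "slope": -2.3058e-05,
  "y_intercept": 1
}
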