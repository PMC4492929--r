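{
  "subset": "large",
  "w0": 2.68491,
  "weights": {
    "d_ie": 0.053,
    "dd_ee": 0.38921,
    "dd_ve": 0.18347,
    "dd_sp": 0.44347,
    "dd_sn": 0,
    "dd_s": 0.1848,
    "dd_hydr": 0.55761,
    "d_hb": 0.03585,
    "interface_mt": 6.37356e-04,
    "dd_sasa_over_interface": 0
  },
  "pvalues": {
    "w0": 0,
    "d_ie": 1.63e-05,
    "dd_ee": 0,
    "dd_ve": 6.66e-16,
    "dd_sp": 2.22e-16,
    "dd_s": 9.72e-03,
    "dd_hydr": 2.10e-05,
    "d_hb": 9.24e-02,
    "interface_mt": 3.04e-06
  },
  "slope": -7.0929e-07,
  "y_intercept": 1
}
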