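{
  "fcrn_endo_conc": 601.68509026518,
  "k_dist": 0.102127484758284,
  "v_endo_ref": 0.0216531578273808,
  "targets": [40311, 110, 0.07],
  "achieved": [40324.0824215375, 110.000007145741, 0.00867967673364991, 0.0700461850484522, 16.3152298253992],
  "residuals": [0.000324537261230606, 6.49612823533374e-08, 0.000659786406459695],
  "objective": 7.25008942399043e-11,
  "convergence": 0
}
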