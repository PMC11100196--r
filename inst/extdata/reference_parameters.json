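{
  "N": 10000000,
  "alpha": 0.0335221130942679,
  "mu": 0.0224076141548718,
  "beta0": 1,
  "w_hcs": 2.31205267977056,
  "w_wdp": 2.48638575723798,
  "w_hec": 2.49998536942739,
  "gamma_min": 0.5,
  "g0": 1,
  "w_et": 0.199897284964083,
  "w_jtp": 0.19089210433746,
  "ii_lookup": {
    "x": [120000, 225000, 260000, 400000],
    "y": [0.0488728802203401, 0.0894495904830338, 0.635762733403118, 0.636762733403118]
  },
  "w_delta": 0.505,
  "idr_ref": 0.5,
  "panel_size": 2000,
  "gp_adjust_time": 1,
  "contract_fee": 100,
  "base_income": 150000,
  "gp_floor": 100,
  "cr0": 0.00376465308161721,
  "intervention_start_year": 2020,
  "dt": 0.0833333333333333,
  "horizon": [2015, 2030],
  "calibration_seed": 43
}
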