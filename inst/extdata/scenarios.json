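{
  "padi4_impa3_fluor": {"generator": "gen_titration", "kd": 3.9, "fixed_conc": 3},
  "padi4_dimpa3_fluor": {"generator": "gen_titration", "kd": 6, "fixed_conc": 3},
  "nls2_impa3_fluor": {"generator": "gen_titration", "kd": 4, "fixed_conc": 3},
  "nls2_dimpa3_fluor": {"generator": "gen_titration", "kd": 4, "fixed_conc": 3},
  "padi4_impa3_itc": {"generator": "gen_itc", "ka": 2.1e5, "dh": -65.5, "n": 0.97},
  "padi4_dimpa3_itc": {"generator": "gen_itc", "ka": 7.8e5, "dh": -38.4, "n": 0.84},
  "nls1_impa3_itc": {"generator": "gen_itc", "ka": 2.3e5, "dh": -21.3, "n": 1.24},
  "nls1_dimpa3_itc": {"generator": "gen_itc", "ka": 6.5e5, "dh": -8.7, "n": 1.22},
  "nls2_impa3_itc": {"generator": "gen_itc", "ka": 0.43e5, "dh": -35.7, "n": 1.08},
  "nls2_dimpa3_itc": {"generator": "gen_itc", "ka": 2.3e5, "dh": -11.2, "n": 1.10},
  "nls1_impa3_bli": {"generator": "gen_bli", "kon": 0.0037, "koff": 0.0685},
  "nls1_dimpa3_bli": {"generator": "gen_bli", "kon": 0.011, "koff": 0.046},
  "nls2_impa3_bli": {"generator": "gen_bli", "kon": 0.003, "koff": 0.32},
  "nls2_dimpa3_bli": {"generator": "gen_bli", "kon": 0.020, "koff": 0.23},
  "nls1_dosy": {"generator": "gen_dosy", "d_list": [8.8e-7, 4e-7], "amp_list": [0.7, 0.3]},
  "nls2_dosy": {"generator": "gen_dosy", "d_list": [9.6e-7], "amp_list": [1.0]},
  "nls1_landscape": {"generator": "gen_affinity_landscape", "seq_length": 27, "start_number": 58, "core_center": 68, "baseline": -6, "core_depth": 2}
}
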