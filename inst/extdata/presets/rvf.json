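{
  "name": "rvf",
  "description": "Calibrated right ventricular failure state",
  "configuration": "BVFS",
  "heart_rate": 60,
  "ventricles": {
    "left": {
      "e_max": 0.619841471213475,
      "e_min": 0.055,
      "v0": 10,
      "p_drive_cap": 80
    },
    "right": {
      "e_max": 0.2113125,
      "e_min": 0.20125,
      "v0": 10,
      "p_drive_cap": 60
    }
  },
  "coupling": {
    "alpha_rl": 0.285173766152844,
    "alpha_lr": 0.071293441538211,
    "transmission_cap": 12,
    "pericardial_enabled": false,
    "pericardial_stiffness": 0.5,
    "pericardial_v0": 400
  },
  "valves": {
    "mitral": 0.005,
    "aortic": 0.01,
    "tricuspid": 0.005,
    "pulmonary": 0.01
  },
  "vascular": {
    "r_upper_body": 1.41758620689655,
    "r_lower_body": 1.41758620689655,
    "r_pulmonary": 0.471843248101012,
    "r_venous_return": 0.08,
    "r_pulm_venous": 0.018,
    "c_la": 4,
    "c_ra": 9,
    "v0_la": 5,
    "v0_ra": 5,
    "clamp_factor": 1
  },
  "chambers": {
    "aoc": {
      "air_volume_ref": 1500,
      "pressure_abs_ref": 760,
      "water_volume_ref": 1000,
      "water_volume": 1110
    },
    "svc": {
      "air_volume_ref": 250,
      "pressure_abs_ref": 760,
      "water_volume_ref": 2100,
      "water_volume": 2105
    },
    "pac": {
      "air_volume_ref": 1200,
      "pressure_abs_ref": 760,
      "water_volume_ref": 1300,
      "water_volume": 1327
    },
    "pvc": {
      "air_volume_ref": 2000,
      "pressure_abs_ref": 760,
      "water_volume_ref": 500,
      "water_volume": 531
    }
  },
  "ecmo": {
    "enabled": false,
    "speed": 3000,
    "return_site": "retrograde_femoral",
    "c0": 1.3e-05,
    "c1": -0.002,
    "c2": -0.6,
    "r_drainage": 0.25,
    "r_return": 0.45,
    "inertance": 0.01
  },
  "fs": {
    "enabled": true,
    "slope_lv": 12,
    "intercept_lv": -83.643706605202,
    "slope_rv": 1.43560344331773,
    "intercept_rv": -15.2096938587519,
    "gain": 0.3,
    "e_max_bounds": {
      "left": [0.1, 10],
      "right": [0.03, 8]
    }
  },
  "waveform": {
    "systolic_fraction": 0.36,
    "n1": 1.32,
    "n2": 21.9,
    "tau1": 0.269,
    "tau2": 0.452
  },
  "initial_state": {
    "v_lv": 154.152388342377,
    "v_rv": 163.222295139784,
    "v_la": 51.0019324242485,
    "v_ra": 289.267255663446,
    "water_aoc": 1104.26927935324,
    "water_svc": 2110.76265966562,
    "water_pac": 1347.03914414219,
    "water_pvc": 531.482209437371,
    "q_ecmo": 0
  },
  "targets": {
    "maop": 62.7,
    "lap": 13.2,
    "rap": 32.2,
    "flow": 2.32
  }
}
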