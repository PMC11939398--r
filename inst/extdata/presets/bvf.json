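{
  "name": "bvf",
  "description": "Calibrated biventricular failure state",
  "configuration": "BVFS",
  "heart_rate": 60,
  "ventricles": {
    "left": {
      "e_max": 0.400274415542826,
      "e_min": 0.149545454545455,
      "v0": 10,
      "p_drive_cap": 80
    },
    "right": {
      "e_max": 0.198333333333333,
      "e_min": 0.188888888888889,
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
    "r_upper_body": 2.24789473684211,
    "r_lower_body": 2.24789473684211,
    "r_pulmonary": 0.07,
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
    "intercept_lv": -310.891105812688,
    "slope_rv": 1.4482340595713,
    "intercept_rv": -16.3731789544977,
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
    "v_lv": 193.255595087888,
    "v_rv": 183.233449256209,
    "v_la": 128.610930904259,
    "v_ra": 308.366021446868,
    "water_aoc": 1108.86205994508,
    "water_svc": 2111.14111025713,
    "water_pac": 1350.36907942259,
    "water_pvc": 579.186954674686,
    "q_ecmo": 0
  },
  "targets": {
    "maop": 64.5,
    "lap": 32.9,
    "rap": 34,
    "flow": 1.52
  }
}
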