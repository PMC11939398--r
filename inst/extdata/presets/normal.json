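{
  "name": "normal",
  "description": "Calibrated normal cardiac state (biventricular + Frank-Starling)",
  "configuration": "BVFS",
  "heart_rate": 60,
  "ventricles": {
    "left": {
      "e_max": 1.10280837146086,
      "e_min": 0.055,
      "v0": 10,
      "p_drive_cap": 80
    },
    "right": {
      "e_max": 0.969703766170617,
      "e_min": 0.05,
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
    "r_upper_body": 1.52,
    "r_lower_body": 1.52,
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
      "air_volume_ref": 284.682470928569,
      "pressure_abs_ref": 760,
      "water_volume_ref": 2065.31752907143,
      "water_volume": 2070.31752907143
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
    "slope_lv": 15.0741713513372,
    "intercept_lv": -100.2430649159,
    "slope_rv": 4.79298577245438,
    "intercept_rv": -10.3312197180595,
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
    "v_lv": 146.117322775413,
    "v_rv": 99.6862173741044,
    "v_la": 40.2684777261616,
    "v_ra": 52.0496451018527,
    "water_aoc": 1101.20858502821,
    "water_svc": 2069.01743999948,
    "water_pac": 1315.19147113089,
    "water_pvc": 523.539883064047,
    "q_ecmo": 0
  },
  "targets": {
    "maop": 63.8,
    "lap": 12,
    "rap": 6.4,
    "flow": 4.1,
    "clamp_ratio": 0.47
  }
}
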