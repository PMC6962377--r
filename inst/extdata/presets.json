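[
  {
    "name": "LN229-Control",
    "cell_line": "LN229",
    "pressure_pa": 0,
    "wound_closure_ctrl": 0.57,
    "wound_closure_exp": 0.57,
    "elongated_fraction": 0.177712,
    "mixture": {
      "weights": [0.85, 0.15],
      "modes": [1.29, 2.12],
      "sigmas": [0.6, 0.2]
    }
  },
  {
    "name": "LN229-Agar",
    "cell_line": "LN229",
    "pressure_pa": 0,
    "wound_closure_ctrl": 0.57,
    "wound_closure_exp": 0.57,
    "elongated_fraction": 0.21,
    "mixture": {
      "weights": [0.860082, 0.139918],
      "modes": [1.32, 2.19],
      "sigmas": [0.6, 0.15]
    }
  },
  {
    "name": "LN229-23Pa",
    "cell_line": "LN229",
    "pressure_pa": 23,
    "wound_closure_ctrl": 0.57,
    "wound_closure_exp": 0.802,
    "elongated_fraction": 0.391,
    "mixture": {
      "weights": [0.712477, 0.287523],
      "modes": [1.37, 2.63],
      "sigmas": [0.6, 0.01]
    }
  },
  {
    "name": "LN229-47Pa",
    "cell_line": "LN229",
    "pressure_pa": 47,
    "wound_closure_ctrl": 0.57,
    "wound_closure_exp": 0.67,
    "elongated_fraction": 0.18201,
    "mixture": {
      "weights": [0.85, 0.15],
      "modes": [1.24, 2.66],
      "sigmas": [0.6, 0.03873]
    }
  },
  {
    "name": "LN229-115Pa",
    "cell_line": "LN229",
    "pressure_pa": 115,
    "wound_closure_ctrl": 0.57,
    "wound_closure_exp": 0.53,
    "elongated_fraction": 0.015084,
    "mixture": {
      "weights": 1,
      "modes": 1.19,
      "sigmas": 0.6
    }
  },
  {
    "name": "U251-Control",
    "cell_line": "U251",
    "pressure_pa": 0,
    "wound_closure_ctrl": 0.367,
    "wound_closure_exp": 0.367,
    "elongated_fraction": 0.330026,
    "mixture": {
      "weights": 1,
      "modes": 1.15,
      "sigmas": 1.174886
    }
  },
  {
    "name": "U251-Agar",
    "cell_line": "U251",
    "pressure_pa": 0,
    "wound_closure_ctrl": 0.367,
    "wound_closure_exp": 0.41,
    "elongated_fraction": 0.216472,
    "mixture": {
      "weights": [0.85, 0.15],
      "modes": [1.18, 1.68],
      "sigmas": [1, 0.25]
    }
  },
  {
    "name": "U251-23Pa",
    "cell_line": "U251",
    "pressure_pa": 23,
    "wound_closure_ctrl": 0.367,
    "wound_closure_exp": 0.545,
    "elongated_fraction": 0.352294,
    "mixture": {
      "weights": 1,
      "modes": 1.24,
      "sigmas": 1.02
    }
  },
  {
    "name": "U251-47Pa",
    "cell_line": "U251",
    "pressure_pa": 47,
    "wound_closure_ctrl": 0.367,
    "wound_closure_exp": 0.447,
    "elongated_fraction": 0.296351,
    "mixture": {
      "weights": 1,
      "modes": 1.14,
      "sigmas": 1.16
    }
  },
  {
    "name": "U251-115Pa",
    "cell_line": "U251",
    "pressure_pa": 115,
    "wound_closure_ctrl": 0.367,
    "wound_closure_exp": 0.503,
    "elongated_fraction": 0.058,
    "mixture": {
      "weights": [0.753618, 0.246382],
      "modes": [1.21, 1.63],
      "sigmas": [0.6, 0.35]
    }
  }
]
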