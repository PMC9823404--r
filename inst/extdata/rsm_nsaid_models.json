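[
  {
    "response": "Y1",
    "analyte": "paracetamol",
    "factors": ["step_potential", "interval_time", "modulation_time", "modulation_amplitude"],
    "intercept": 1.747,
    "linear": [0.22, 0.352, -0.935, 1.082],
    "quadratic": [-0.476, -0.431, -0.308, -0.012],
    "interaction": [-0.309, 0.211, 0.209, 0.297, 0.66, 1.507]
  },
  {
    "response": "Y2",
    "analyte": "diclofenac",
    "factors": ["step_potential", "interval_time", "modulation_time", "modulation_amplitude"],
    "intercept": 1.06,
    "linear": [0.069, 0.278, -0.539, 0.613],
    "quadratic": [-0.393, -0.353, -0.153, 0.01],
    "interaction": [0.105, 0.123, 0.156, 0.223, 0.373, -0.885]
  },
  {
    "response": "Y3",
    "analyte": "naproxen+aspirin",
    "factors": ["step_potential", "interval_time", "modulation_time", "modulation_amplitude"],
    "intercept": 0.626,
    "linear": [0.204, 0.13, -0.318, 0.49],
    "quadratic": [-0.014, -0.125, -0.007, -0.055],
    "interaction": [-0.144, 0.201, 0.296, 0.242, 0.377, -0.554]
  }
]
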