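[
  {"name": "Na", "unit": "mmol/L", "molar_mass": 22.99, "ri_low": 138, "ri_high": 145, "reporting_decimals": 0},
  {"name": "K",  "unit": "mmol/L", "molar_mass": 39.10, "ri_low": 3.6, "ri_high": 4.8, "reporting_decimals": 1},
  {"name": "Ca", "unit": "mg/dL",  "molar_mass": 40.08, "ri_low": 8.8, "ri_high": 10.1, "reporting_decimals": 1},
  {"name": "P",  "unit": "mg/dL",  "molar_mass": 30.97, "ri_low": 2.7, "ri_high": 4.6, "reporting_decimals": 1},
  {"name": "Mg", "unit": "mg/dL",  "molar_mass": 24.31, "ri_low": 1.8, "ri_high": 2.5, "reporting_decimals": 1},
  {"name": "Fe", "unit": "ug/dL",  "molar_mass": 55.85, "ri_low": 40,  "ri_high": 188, "reporting_decimals": 0},
  {"name": "Zn", "unit": "ug/dL",  "molar_mass": 65.38, "ri_low": 80,  "ri_high": 130, "reporting_decimals": 0},
  {"name": "Cu", "unit": "ug/dL",  "molar_mass": 63.55, "ri_low": 71,  "ri_high": 132, "reporting_decimals": 0}
]
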