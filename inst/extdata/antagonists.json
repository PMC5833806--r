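[
  {"name": "ABT-199", "target": "BCL2", "kd_nM": 0.01,
   "bioavailability_factor": 0.5,
   "note": "literature-typical affinity; override with an assay-specific constant where available"},
  {"name": "WEHI-539", "target": "BCLXL", "kd_nM": 1.1,
   "bioavailability_factor": 0.5,
   "note": "literature-typical affinity; override with an assay-specific constant where available"},
  {"name": "A-1210477", "target": "MCL1", "kd_nM": 0.45,
   "bioavailability_factor": 0.5,
   "note": "literature-typical affinity; override with an assay-specific constant where available"}
]
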