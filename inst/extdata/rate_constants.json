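{
  "comment": "Rate constants of the EDC-driven reaction cycle, calibrated against the printed observables of the standard conditions (23 mM precursor, 200 mM MES pH 5.3, 25 C): peak anhydride 0.9 mM at 7.5 mM fuel; anhydride peak near 3 min and clearance of the 0.9 mM coacervation threshold near 18 min at 25 mM fuel; 1.7 mM filtrate anhydride ~55% of total at 2 min.",
  "units": {
    "k0": "per_minute",
    "k1": "per_mM_per_minute",
    "k2": "per_minute",
    "k3": "per_minute",
    "k4": "per_minute"
  },
  "k0": 0.082262,
  "k1": 0.0442616,
  "k2": 1.31917,
  "k3": 6.34313,
  "k4": 0.0906518
}
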