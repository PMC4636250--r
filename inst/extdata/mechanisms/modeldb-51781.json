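{
  "name": "modeldb-51781",
  "description": "Best-effort transcription of the granule-cell channel conductance densities of the Santhakumar et al. (2005) dentate gyrus network model (ModelDB accession 51781; cell biophysics after Aradi & Holmes 1998): Na, fast and slow delayed-rectifier K, A-type K, T-/N-/L-type Ca and Ca-dependent SK/BK channels with layer-specific densities. Channel kinetics are represented by this package's channel forms with matched activation ranges, so quantitative fidelity is limited to that of the transcription; use fallback-hh for calibrated qualitative work.",
  "passive": {
    "cm_uF_cm2": 1.0,
    "Ra_ohm_cm": 210,
    "g_leak_S_cm2": {"soma": 4e-05, "GCL": 4e-05, "IML": 4e-05, "MML": 4e-05, "OML": 4e-05},
    "e_leak_mV": -75
  },
  "reversals_mV": {"na": 45, "k": -85, "ca": 80},
  "ca_pool": {"tau_ms": 10, "ca0_mM": 5e-05, "depth_um": 0.2},
  "densities_S_cm2": {
    "na":   {"soma": 0.12,   "GCL": 0.018,  "IML": 0.013,  "MML": 0.008,  "OML": 0.0},
    "kdrf": {"soma": 0.016,  "GCL": 0.004,  "IML": 0.004,  "MML": 0.001,  "OML": 0.001},
    "kdrs": {"soma": 0.006,  "GCL": 0.006,  "IML": 0.006,  "MML": 0.006,  "OML": 0.008},
    "ka":   {"soma": 0.012,  "GCL": 0.008,  "IML": 0.008,  "MML": 0.001,  "OML": 0.001},
    "cat":  {"soma": 3.7e-05,"GCL": 7.5e-05,"IML": 2.5e-04,"MML": 5e-04,  "OML": 0.001},
    "can":  {"soma": 0.002,  "GCL": 0.003,  "IML": 0.001,  "MML": 0.001,  "OML": 0.001},
    "cal":  {"soma": 0.005,  "GCL": 0.0075, "IML": 0.0075, "MML": 5e-04,  "OML": 0.0},
    "sk":   {"soma": 0.001,  "GCL": 4e-04,  "IML": 2e-04,  "MML": 0.0,    "OML": 0.0},
    "bk":   {"soma": 6e-04,  "GCL": 6e-04,  "IML": 6e-04,  "MML": 0.0024, "OML": 0.0024}
  }
}
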