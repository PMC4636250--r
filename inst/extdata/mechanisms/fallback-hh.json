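{
  "name": "fallback-hh",
  "description": "Simplified Hodgkin-Huxley-style mechanism set authored for this package (qualitative mode): Na + fast delayed-rectifier K + leak everywhere, with a generic high-threshold Ca channel and an SK-type Ca-activated K channel in soma and dendrites. Densities calibrated for a stable rest near -75 mV, somatic spiking with ~5-8 ms refractoriness, and active back-propagation that crosses -37 mV in the outer molecular layer.",
  "passive": {
    "cm_uF_cm2": 1.0,
    "Ra_ohm_cm": 210,
    "g_leak_S_cm2": {
      "soma": 5e-05,
      "GCL": 5e-05,
      "IML": 5e-05,
      "MML": 5e-05,
      "OML": 5e-05
    },
    "e_leak_mV": -75
  },
  "reversals_mV": {
    "na": 55,
    "k": -80,
    "ca": 80
  },
  "ca_pool": {
    "tau_ms": 120,
    "ca0_mM": 5e-05,
    "depth_um": 0.2
  },
  "kinetics": {
    "na_h_scale": 0.6
  },
  "densities_S_cm2": {
    "na": {
      "soma": 0.12,
      "GCL": 0.01,
      "IML": 0.006,
      "MML": 0.005,
      "OML": 0.005
    },
    "kdrf": {
      "soma": 0.06,
      "GCL": 0.015,
      "IML": 0.01,
      "MML": 0.008,
      "OML": 0.007
    },
    "can": {
      "soma": 0.0001,
      "GCL": 0.0001,
      "IML": 0.0001,
      "MML": 0.0001,
      "OML": 0.0001
    },
    "sk": {
      "soma": 0.0003,
      "GCL": 5e-05,
      "IML": 5e-05,
      "MML": 5e-05,
      "OML": 5e-05
    }
  }
}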