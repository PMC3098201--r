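{
  "ml_type1": {
    "model": "morris_lecar",
    "type_label": "I",
    "cm": 20.0,
    "g_l": 2.0, "e_l": -60.0,
    "g_ca": 4.0, "e_ca": 120.0,
    "g_k": 8.0, "e_k": -84.0,
    "v1": -1.2, "v2": 18.0,
    "v3": 12.0, "v4": 17.4,
    "phi_w": 0.06666666666666667,
    "dt": 0.10,
    "spike_threshold": -20.0
  },
  "ml_type2": {
    "model": "morris_lecar",
    "type_label": "II",
    "cm": 20.0,
    "g_l": 2.0, "e_l": -60.0,
    "g_ca": 4.4, "e_ca": 120.0,
    "g_k": 8.0, "e_k": -84.0,
    "v1": -1.2, "v2": 18.0,
    "v3": 2.0, "v4": 30.0,
    "phi_w": 0.04,
    "dt": 0.10,
    "spike_threshold": -20.0
  },
  "pyr_type1": {
    "model": "pyramidal",
    "type_label": "I",
    "cm": 1.0,
    "g_na": 24.0, "e_na": 55.0,
    "g_kdr": 3.0, "e_k": -90.0,
    "g_ks": 0.0,
    "g_l": 0.02, "e_l": -70.0,
    "m_half": -30.0, "m_slope": 9.5,
    "h_half": -53.0, "h_slope": -7.0,
    "tau_h0": 0.37, "tau_h1": 2.78, "tau_h_half": -40.5, "tau_h_slope": 6.0,
    "n_half": -30.0, "n_slope": 10.0,
    "tau_n0": 0.37, "tau_n1": 1.85, "tau_n_half": -27.0, "tau_n_slope": 15.0,
    "z_half": -39.0, "z_slope": 5.0,
    "tau_z": 75.0,
    "r_h": 1.0, "r_z": 1.0,
    "dt": 0.05,
    "spike_threshold": -20.0
  },
  "pyr_type2": {
    "model": "pyramidal",
    "type_label": "II",
    "cm": 1.0,
    "g_na": 24.0, "e_na": 55.0,
    "g_kdr": 3.0, "e_k": -90.0,
    "g_ks": 1.5,
    "g_l": 0.02, "e_l": -70.0,
    "m_half": -30.0, "m_slope": 9.5,
    "h_half": -53.0, "h_slope": -7.0,
    "tau_h0": 0.37, "tau_h1": 2.78, "tau_h_half": -40.5, "tau_h_slope": 6.0,
    "n_half": -30.0, "n_slope": 10.0,
    "tau_n0": 0.37, "tau_n1": 1.85, "tau_n_half": -27.0, "tau_n_slope": 15.0,
    "z_half": -39.0, "z_slope": 5.0,
    "tau_z": 75.0,
    "r_h": 1.0, "r_z": 1.0,
    "dt": 0.05,
    "spike_threshold": -20.0
  },
  "stimulus": {
    "prc_pulse": {
      "pyr_type1": {"amplitude": 3.0, "duration": 0.06},
      "pyr_type2": {"amplitude": 10.0, "duration": 0.06},
      "ml_type1": {"amplitude": 100.0, "duration": 0.50},
      "ml_type2": {"amplitude": 100.0, "duration": 0.50}
    },
    "poisson_pulse": {
      "amplitude": 30.0, "duration": 0.2,
      "baseline_type1": 0.0, "baseline_type2": 0.5
    }
  },
  "network": {
    "n": 200, "k": 4,
    "duration": 10000.0, "discard": 3000.0,
    "synapse_tau": 2.0,
    "spike_threshold": -20.0,
    "freq_sd_target": 1.0
  }
}
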