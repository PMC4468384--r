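{
  "n_per_type": 100,
  "dt": 0.5,
  "populations": {
    "osn": {
      "tau": 5,
      "beta": 1,
      "theta_min": 0,
      "theta_max": 15,
      "is_spiking": false,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 0,
      "tau_ahc": 100,
      "e_ahc": -15
    },
    "pg": {
      "tau": 2,
      "beta": 1,
      "theta_min": 0,
      "theta_max": 4,
      "is_spiking": false,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 0,
      "tau_ahc": 100,
      "e_ahc": -15
    },
    "mi_apical": {
      "tau": 4,
      "beta": 2,
      "theta_min": -1.4,
      "theta_max": 9,
      "is_spiking": false,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 0,
      "tau_ahc": 100,
      "e_ahc": -15
    },
    "mi": {
      "tau": 5,
      "beta": 2,
      "theta_min": -1.4,
      "theta_max": 9,
      "is_spiking": true,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 0,
      "tau_ahc": 100,
      "e_ahc": -15
    },
    "gr": {
      "tau": 5,
      "beta": 2,
      "theta_min": -1,
      "theta_max": 6,
      "is_spiking": true,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 0,
      "tau_ahc": 100,
      "e_ahc": -15
    },
    "ff": {
      "tau": 5,
      "beta": 1,
      "theta_min": 0,
      "theta_max": 15,
      "is_spiking": true,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 0,
      "tau_ahc": 100,
      "e_ahc": -15
    },
    "pyr": {
      "tau": 10,
      "beta": 2,
      "theta_min": 0,
      "theta_max": 15,
      "is_spiking": true,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 40,
      "tau_ahc": 100,
      "e_ahc": -15
    },
    "fb": {
      "tau": 5,
      "beta": 2,
      "theta_min": 0,
      "theta_max": 15,
      "is_spiking": true,
      "v_hyper": -10,
      "t_refrac": 2,
      "a_ahc": 0,
      "tau_ahc": 100,
      "e_ahc": -15
    }
  },
  "pathways": {
    "osn_pg": {
      "g_max": 0.166,
      "e_nernst": 70,
      "tau1": 1,
      "tau2": 2
    },
    "osn_mi": {
      "g_max": 0.16,
      "e_nernst": 70,
      "tau1": 1,
      "tau2": 2
    },
    "pg_mi": {
      "g_max": 0.38,
      "e_nernst": -10,
      "tau1": 4,
      "tau2": 8
    },
    "mi_gr": {
      "g_max": 0.02,
      "e_nernst": 70,
      "tau1": 1,
      "tau2": 2
    },
    "gr_mi": {
      "g_max": 0.18,
      "e_nernst": -10,
      "tau1": 4,
      "tau2": 8
    },
    "mi_ff": {
      "g_max": 0.2,
      "e_nernst": 70,
      "tau1": 1,
      "tau2": 2
    },
    "mi_pyr": {
      "g_max": 0.76,
      "e_nernst": 70,
      "tau1": 1,
      "tau2": 2
    },
    "ff_pyr": {
      "g_max": 0.055,
      "e_nernst": -10,
      "tau1": 4,
      "tau2": 8
    },
    "pyr_fb": {
      "g_max": 0.25,
      "e_nernst": 70,
      "tau1": 1,
      "tau2": 2
    },
    "fb_pyr": {
      "g_max": 0.55,
      "e_nernst": -10,
      "tau1": 4,
      "tau2": 8
    },
    "pyr_pyr": {
      "g_max": 510,
      "e_nernst": 70,
      "tau1": 1,
      "tau2": 2
    }
  },
  "modulation": {
    "mi_theta_max": {
      "off": 9,
      "on": 1,
      "curve": "alpha1_mi",
      "locus": "ob"
    },
    "gr_theta_min_a1": {
      "off": -1,
      "on": -2.4,
      "curve": "alpha1_gr",
      "locus": "ob"
    },
    "gr_theta_min_a2": {
      "off": 0,
      "on": 1,
      "curve": "alpha2_gr",
      "locus": "ob"
    },
    "fb_theta_min": {
      "off": 0,
      "on": -0.1,
      "curve": "cortical",
      "locus": "pc"
    },
    "pyr_fb_gmax": {
      "off": 0.25,
      "on": 0.06,
      "curve": "cortical",
      "locus": "pc"
    },
    "pyr_pyr_gmax": {
      "off": 510,
      "on": 260,
      "curve": "cortical",
      "locus": "pc"
    },
    "pyr_a_ahc": {
      "off": 40,
      "on": 0,
      "curve": "cortical",
      "locus": "pc"
    }
  },
  "receptor_y_half": {
    "alpha2_gr": 0.1,
    "alpha1_gr": 10,
    "alpha1_mi": 10,
    "cortical": 10
  },
  "connectivity": {
    "mi_gr_frac": 0.4,
    "mi_pyr_frac": 0.2,
    "mi_ff_frac": 0.4,
    "ff_pyr_frac": 0.3,
    "pyr_pyr_frac": 0.2,
    "pyr_fb_frac": 0.2,
    "fb_pyr_frac": 0.2
  },
  "plasticity": {
    "tau_pp": 800,
    "tau_post": 2,
    "tau_nmda_f": 7,
    "tau_nmda_r": 1,
    "t_delay": 1,
    "w_init_max": 0.04,
    "glu_form": "rise_fall"
  },
  "dynamics": {
    "spike_rate_unit_ms": 1,
    "membrane_noise_sd_mv": 3
  },
  "odor": {
    "n": 100,
    "mu": 50,
    "sigma": 10,
    "theta_max_osn": 15,
    "osn_gain": 4,
    "osn_baseline_mv": 0.5
  }
}
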