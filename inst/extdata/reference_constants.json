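{
  "description": "Reference constants of the electro-mechanical cell model: electrophysiology follows the ten Tusscher-Panfilov 2006 human ventricular formulation (fixed constants compiled into the model); the values here are the tuned ryanodine-receptor gate, calcium-transfer and contractile-block constants, frozen so that the all-ones scaling vector satisfies every packaged calibration range.",
  "length_convention": "cell length as fraction of L_max; sarcomere length = 2.23 um * L/L_max",
  "force_normalization": {
    "reference_peak_isometric_force_raw": 0.124712356,
    "note": "raw-unit peak active force of the reference model at 0.93 L_max after 200 cycles at 1 Hz; all reported forces are divided by this value"
  },
  "modified_base_constants": {
    "Vmaxup_mM_per_ms": 0.012,
    "Vleak_per_ms": 0.00015,
    "Vxfer_per_ms": 0.005,
    "Bufc_mM": 0.35,
    "Bufsr_mM": 5,
    "Gto_nS_per_pF": 0.073,
    "GKs_nS_per_pF": 0.392,
    "note": "SERCA, leak, subspace-transfer and buffer constants retuned for the Markov release gate"
  },
  "ryanodine_receptor": {
    "ks_base_per_ms": 0.08,
    "k1_prime_per_mM2_ms": 1.1,
    "k2_prime_per_mM_ms": 0.04,
    "kom_base_per_ms": 0.6,
    "kim_base_per_ms": 0.01,
    "luminal_gain": {
      "maxsr": 8,
      "minsr": 1,
      "EC50_mM": 3.5,
      "hill": 4
    },
    "refractory_Cass_uM": 0.5,
    "note": "opening scaled down / inactivation scaled up at low SR load (quartic luminal dependence); recovery to the available state is inhibited while subspace Ca2+ exceeds the refractory threshold"
  },
  "mechanics": {
    "beta_se": 0.2,
    "alpha_se": 60,
    "beta_pe": 0.03,
    "alpha_pe": 15,
    "L_pe0": 0.8,
    "F_xb": 2,
    "v_h": 0.001,
    "a_h": 0.25,
    "eps_f": 0.001,
    "k_p": 0.0025,
    "k_m": 0.03,
    "c_v": 3,
    "s_ov": 15,
    "l_half": 0.78,
    "a_on": 150,
    "a_off": 0.21,
    "k_coop": 3.3,
    "c_bb": 1,
    "B_tot": 0.07,
    "b_50": 0.4,
    "n_hill": 3
  },
  "stimulus": {
    "amplitude_pA_per_pF": -52,
    "duration_ms": 1,
    "note": "about twice the diastolic threshold of the reference model"
  }
}
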