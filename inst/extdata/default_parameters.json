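{
  "comment": "Default parameter values, fitted-parameter registry and bounds. Units: time ms, stress kPa, calcium uM, resistances mmHg ms/mL.",
  "tanh": {
    "Smax_ref": 38, "tauSR_ref": 110, "tauSD": 45, "tCR": 500,
    "ld_smax": 0, "ld_tau": 0
  },
  "rice": { "Ca_res": 0.076, "Ca_max": 0.9, "tauCR": 164.4, "tauCD": 149.0 },
  "land": {
    "Tref": 120, "Ca50_ref": 0.501, "nTRPN": 3.22, "kTRPN": 0.1,
    "nTm": 5.47, "kUW": 0.046, "kWS": 0.012, "beta0": 2.3, "beta1": -1.21,
    "TRPN50": 0.35, "ku": 0.04, "rw": 0.5, "rs": 0.25, "TotA": 25,
    "gammaW": 0.615, "gammaS": 0.0085, "phi": 2.23
  },
  "land-passive": { "a_p": 42, "b": 9.1, "k": 7, "eta_l": 200, "eta_s": 20 },
  "valves": { "R_AVf": 60, "R_MVf": 40, "R_AVb": 1000, "R_MVb": 1000 },
  "windkessel": { "R1": 40, "R2": 1100, "C": 1.0 },
  "fitted": {
    "names": ["nTRPN", "beta1", "nTm", "Ca50_ref", "kUW",
              "Ca_res", "Ca_max", "tauCR", "tauCD", "a_p"],
    "bounds_note": "lower/upper are +/-50% of the defaults",
    "lower": [1.61, -1.815, 2.735, 0.2505, 0.023, 0.038, 0.45, 82.2, 74.5, 21],
    "upper": [4.83, -0.605, 8.205, 0.7515, 0.069, 0.114, 1.35, 246.6, 223.5, 63]
  }
}
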