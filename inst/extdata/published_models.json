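{
  "version": "1.0",
  "note": "Published multiple-regression equations predicting log-log residual slaughter yields from morphological predictors P1-P5. Predictors: P1 = head area / total body area, P2 = ultrasound E8 / height between landmarks 8-9, P3 = caudal area / ventral area, P4 = body weight (g), P5 = % muscle fat.",
  "models": {
    "Mod_hlCarss": {
      "response": "Logr_hlCarss",
      "intercept": -0.06,
      "coefficients": { "P1": -0.37, "P2": 6.12, "P3": 0.06 }
    },
    "Mod_Fil": {
      "response": "Logr_Fil",
      "intercept": -0.02,
      "coefficients": { "P1": -0.63, "P2": 5.30, "P3": 0.06, "P4": -7.84e-06, "P5": 0.0007 }
    }
  }
}
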