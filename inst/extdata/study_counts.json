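{
  "name": "paired_noise_field_study_counts",
  "version": 1,
  "description": "Published per-stage outcome counts of the paired CG vs analog noise-field study: agreement categories per noise, both-detected totals, and preference counts among both-detected eyes. analog-only detections were absent (every analog-detected eye was also CG-detected), the unique paired structure consistent with the published marginals.",
  "normal": {
    "n": 35,
    "cg": {"agreement": 0, "partial": 0, "no_agreement": 1, "no_response": 34},
    "analog": {"agreement": 0, "partial": 0, "no_agreement": 0, "no_response": 35}
  },
  "ppg": {
    "n": 19,
    "cg": {"agreement": 0, "partial": 0, "no_agreement": 0, "no_response": 19},
    "analog": {"agreement": 0, "partial": 0, "no_agreement": 0, "no_response": 19}
  },
  "glaucoma": {
    "M1": {
      "n": 97,
      "cg": {"agreement": 45, "partial": 21, "no_agreement": 0, "no_response": 31},
      "analog": {"agreement": 35, "partial": 14, "no_agreement": 0, "no_response": 48},
      "both_detected": 49,
      "preference": {"cg": 37, "same": 10, "analog": 2}
    },
    "M2": {
      "n": 55,
      "cg": {"agreement": 38, "partial": 13, "no_agreement": 0, "no_response": 4},
      "analog": {"agreement": 32, "partial": 12, "no_agreement": 0, "no_response": 11},
      "both_detected": 44,
      "preference": {"cg": 29, "same": 10, "analog": 5}
    },
    "M3": {
      "n": 33,
      "cg": {"agreement": 17, "partial": 14, "no_agreement": 0, "no_response": 2},
      "analog": {"agreement": 15, "partial": 11, "no_agreement": 0, "no_response": 7},
      "both_detected": 26,
      "preference": {"cg": 19, "same": 5, "analog": 2}
    },
    "M4": {
      "n": 20,
      "cg": {"agreement": 16, "partial": 1, "no_agreement": 0, "no_response": 3},
      "analog": {"agreement": 14, "partial": 1, "no_agreement": 0, "no_response": 5},
      "both_detected": 15,
      "preference": {"cg": 9, "same": 5, "analog": 1}
    }
  }
}
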