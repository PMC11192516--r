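{
  "master_seed": 20240603,
  "paradigm": {
    "syllable_dur_s": 0.32,
    "words_per_sentence": 4,
    "sentences_per_trial": 12,
    "n_trials": 10,
    "drop_first_sentence": true,
    "fs_hz": 500
  },
  "montage": {
    "preset": "desk24"
  },
  "cohort": {
    "n_subjects": 22,
    "coupling_rho": 0.45,
    "groups": ["NL", "SL"]
  },
  "n400": {
    "n_sentences_per_condition": 16,
    "soa_s": 2.5
  },
  "preprocess": {
    "entrainment_band_hz": [0.1, 25],
    "n400_band_hz": [0.1, 30],
    "reject_threshold_uv": 75,
    "exclude_channels": ["T7", "T8", "TP7", "TP8"],
    "frontal_exclude": ["Fp1", "Fp2"],
    "mastoids": ["TP9", "TP10"],
    "bad_channels": []
  },
  "erp": {
    "roi": ["C5", "C3", "C1", "Cz", "C2", "C4", "C6", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6"],
    "windows_ms": [
      [300, 500],
      [500, 700]
    ],
    "fdr_q": 0.05
  },
  "correlation": {
    "group": "SL",
    "pairs": [
      ["sentential_db", "listening_score"],
      ["sentential_db", "n400_late_uv"],
      ["sentential_db", "comprehension_rating"]
    ]
  }
}
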