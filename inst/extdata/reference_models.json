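{
  "iolm_od": {
    "description": "Published OD regression: postoperative CASIA real-power (C0, C45) from preoperative IOLM keratometric (C0, C45), trained on N = 62 eyes",
    "eye_side": "OD",
    "matrix": [[0.9150, -0.0472], [-0.0018, 0.6952]],
    "intercept": [-0.1823, -0.0229],
    "logL": -57.1781,
    "n": 62
  },
  "iolm_os": {
    "description": "Published OS counterpart of iolm_od (off-diagonals and second intercept negated)",
    "eye_side": "OS",
    "matrix": [[0.9150, 0.0472], [0.0018, 0.6952]],
    "intercept": [-0.1823, 0.0229],
    "logL": -57.1781,
    "n": 62
  },
  "casia_od": {
    "description": "Published OD regression: postoperative CASIA real-power (C0, C45) from preoperative CASIA keratometric (C0, C45), trained on N = 62 eyes",
    "eye_side": "OD",
    "matrix": [[1.0253, -0.0023], [-0.0473, 0.8774]],
    "intercept": [-0.2716, -0.2716],
    "logL": -37.8488,
    "n": 62
  },
  "casia_os": {
    "description": "Published OS counterpart of casia_od (off-diagonals and second intercept negated)",
    "eye_side": "OS",
    "matrix": [[1.0253, 0.0023], [0.0473, 0.8774]],
    "intercept": [-0.2716, 0.2716],
    "logL": -37.8488,
    "n": 62
  }
}
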