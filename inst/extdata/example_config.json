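{
  "task": "signal",
  "mode": "multi_charge",
  "peptide_sequence": "KKAAAAAAAADD",
  "pH": 7.4,
  "euler_deg": [0, 0, 0],
  "lambda_D_nm": 2.0,
  "N_mol": "auto",
  "seed": 1
}
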