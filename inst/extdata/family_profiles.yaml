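# Peptide family classification profiles. Rules are evaluated in the order
# given by `precedence` (most specific first); the first rule that fires
# names the family, all satisfied rules are recorded as evidence.
precedence:
  - insulin_like
  - vasopressin
  - GPB5
  - pedal_orcokinin_FDSIG
  - NPF
vasopressin:
  cys_positions: [1, 6]
  length_min: 9
  length_max: 16
GPB5:
  length_min: 80
  length_max: 130
  min_cys: 9
pedal_orcokinin_FDSIG:
  motif: "IG.G"
  length_min: 10
  length_max: 16
NPF:
  cterm_motif: "R.R[FY]$"
  length_min: 30
  length_max: 40
  min_sulfated_tyr: 2
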