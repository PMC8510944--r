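cohort_table1.csv is a transcription of the published necropsy table of the
17-swine confined-space blast study this package models (6 animals with body
armor, 11 without; nominal driving pressure 3.0 MPa). Columns:

  id                  animal number (1-17, published circled numbering)
  body_weight_kg      body weight at exposure, kg
  body_armor          Yes/No - ceramic-plate bulletproof vest worn
  organ_damage        free-text necropsy remark; abbreviations:
                      LH lung hemorrhage, IAH intra-abdominal hemorrhage,
                      BR bladder rupture
  respiratory_arrest  Yes/No - apnea immediately after exposure
  outcome             Survival/Death at 3 h post-injury

Parse with blasttube::cohort_table1().
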