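{
  "n_orthogroups": 34135,
  "n_species_specific_orthogroups": 9178,
  "n_all_species_orthogroups": 8753,
  "n_single_copy_orthogroups": 321,
  "n_category_II": 1055,
  "n_category_III": 324,
  "n_category_IV": 890
}
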