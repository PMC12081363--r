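{
  "default": [
    {
      "drug": "Penicillin",
      "scope": "all_properties",
      "reason": "row prints a single value (344.390) under the En column with every other cell blank; implausible as an enthalpy and treated as a data-entry misalignment, so the row is dropped from all property regressions (its descriptor row is kept)"
    }
  ],
  "optional": [
    {
      "drug": "Carbapanem",
      "scope": "all_properties",
      "toggle": "drop_carbapenem",
      "reason": "molecular weight printed as 153.135 g/mol, chemically implausible for C18H29N3O5S; excluding this row reproduces the published molecular-weight fits"
    },
    {
      "drug": "Levaquin",
      "scope": "MR",
      "toggle": "drop_levaquin_mr",
      "reason": "molar refractivity printed as 91.1 ± 70.4 (uncertainty comparable to the value); excluding it together with Carbapanem reproduces the published molar-refractivity fits to four decimals"
    }
  ]
}
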