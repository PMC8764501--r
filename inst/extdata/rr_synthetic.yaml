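# SYNTHETIC relative-risk configuration.
#
# Site list and ICD-10 code sets follow the standard alcohol-cancer site
# selection (core set) plus the three sensitivity-analysis sites.
# The rr values are NOT the meta-analytic estimates: they are synthetic
# stand-ins back-calculated from the published Argentine 2018 sex-level
# consumption prevalences and per-level attributable fractions, so that
# the default pipeline reproduces the published attributable-fraction
# structure. Non-significant associations carry significant: false and are
# censored to RR = 1 by the pipeline regardless of the value stored here.
sites:
  - site: oral_pharynx
    label: "Oral cavity and pharynx"
    icd10: "C00-C14"
    sexes: "M,F"
    in_core_set: true
  - site: esophagus
    label: "Esophageal cancer"
    icd10: "C15"
    sexes: "M,F"
    in_core_set: true
  - site: colorectal
    label: "Colorectal cancer"
    icd10: "C18-C20"
    sexes: "M,F"
    in_core_set: true
  - site: liver
    label: "Liver cancer"
    icd10: "C22"
    sexes: "M,F"
    in_core_set: true
  - site: larynx
    label: "Larynx cancer"
    icd10: "C32"
    sexes: "M,F"
    in_core_set: true
  - site: breast
    label: "Breast cancer"
    icd10: "C50"
    sexes: "F"
    in_core_set: true
  - site: melanoma
    label: "Melanoma of skin"
    icd10: "C43"
    sexes: "M,F"
    in_core_set: false
  - site: pancreas
    label: "Pancreatic cancer"
    icd10: "C25"
    sexes: "M,F"
    in_core_set: false
  - site: prostate
    label: "Prostate cancer"
    icd10: "C61"
    sexes: "M"
    in_core_set: false

relative_risks:
  # --- core sites, men ---
  - {site: oral_pharynx, sex: M, level: light,    rr: 1.260, significant: true}
  - {site: oral_pharynx, sex: M, level: moderate, rr: 2.536, significant: true}
  - {site: oral_pharynx, sex: M, level: heavy,    rr: 6.981, significant: true}
  - {site: esophagus,    sex: M, level: light,    rr: 1.482, significant: true}
  - {site: esophagus,    sex: M, level: moderate, rr: 3.039, significant: true}
  - {site: esophagus,    sex: M, level: heavy,    rr: 6.834, significant: true}
  - {site: colorectal,   sex: M, level: light,    rr: 1.080, significant: false}
  - {site: colorectal,   sex: M, level: moderate, rr: 1.256, significant: true}
  - {site: colorectal,   sex: M, level: heavy,    rr: 1.592, significant: true}
  - {site: liver,        sex: M, level: light,    rr: 1.060, significant: false}
  - {site: liver,        sex: M, level: moderate, rr: 1.130, significant: false}
  - {site: liver,        sex: M, level: heavy,    rr: 1.687, significant: true}
  - {site: larynx,       sex: M, level: light,    rr: 0.940, significant: false}
  - {site: larynx,       sex: M, level: moderate, rr: 1.613, significant: true}
  - {site: larynx,       sex: M, level: heavy,    rr: 2.963, significant: true}
  # --- core sites, women ---
  - {site: oral_pharynx, sex: F, level: light,    rr: 1.090, significant: false}
  - {site: oral_pharynx, sex: F, level: moderate, rr: 1.629, significant: true}
  - {site: oral_pharynx, sex: F, level: heavy,    rr: 3.264, significant: true}
  - {site: breast,       sex: F, level: light,    rr: 1.037, significant: true}
  - {site: breast,       sex: F, level: moderate, rr: 1.233, significant: true}
  - {site: breast,       sex: F, level: heavy,    rr: 1.319, significant: true}
  - {site: esophagus,    sex: F, level: light,    rr: 1.150, significant: false}
  - {site: esophagus,    sex: F, level: moderate, rr: 2.054, significant: true}
  - {site: esophagus,    sex: F, level: heavy,    rr: 4.036, significant: true}
  - {site: colorectal,   sex: F, level: light,    rr: 1.050, significant: false}
  - {site: colorectal,   sex: F, level: moderate, rr: 1.120, significant: false}
  - {site: colorectal,   sex: F, level: heavy,    rr: 1.240, significant: false}
  - {site: liver,        sex: F, level: light,    rr: 1.020, significant: false}
  - {site: liver,        sex: F, level: moderate, rr: 1.100, significant: false}
  - {site: liver,        sex: F, level: heavy,    rr: 2.005, significant: true}
  - {site: larynx,       sex: F, level: light,    rr: 0.910, significant: false}
  - {site: larynx,       sex: F, level: moderate, rr: 1.430, significant: true}
  - {site: larynx,       sex: F, level: heavy,    rr: 1.320, significant: false}
  # --- sensitivity-analysis sites (plausible magnitudes, synthetic) ---
  - {site: melanoma, sex: M, level: light,    rr: 1.020, significant: false}
  - {site: melanoma, sex: M, level: moderate, rr: 1.100, significant: true}
  - {site: melanoma, sex: M, level: heavy,    rr: 1.250, significant: true}
  - {site: melanoma, sex: F, level: light,    rr: 1.020, significant: false}
  - {site: melanoma, sex: F, level: moderate, rr: 1.100, significant: true}
  - {site: melanoma, sex: F, level: heavy,    rr: 1.250, significant: true}
  - {site: pancreas, sex: M, level: light,    rr: 0.970, significant: false}
  - {site: pancreas, sex: M, level: moderate, rr: 1.070, significant: true}
  - {site: pancreas, sex: M, level: heavy,    rr: 1.190, significant: true}
  - {site: pancreas, sex: F, level: light,    rr: 0.970, significant: false}
  - {site: pancreas, sex: F, level: moderate, rr: 1.070, significant: true}
  - {site: pancreas, sex: F, level: heavy,    rr: 1.190, significant: true}
  - {site: prostate, sex: M, level: light,    rr: 1.030, significant: true}
  - {site: prostate, sex: M, level: moderate, rr: 1.070, significant: true}
  - {site: prostate, sex: M, level: heavy,    rr: 1.180, significant: true}
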