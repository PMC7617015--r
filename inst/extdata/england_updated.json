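{
  "name": "england_updated",
  "comment": "Updated parameterisation for an English validation cohort. Baseline survival, recalibration slopes and the absent-predictor beta/prevalence pairs are the published updated values. Betas listed under placeholder_betas are NOT the development-study weights (those are published in the original development study) and must be replaced before real-data use.",
  "placeholder_betas": ["gender", "age_at_release", "immigrant_status", "incarceration_length", "violent_index_offence", "previous_violent_crime", "civil_status", "employment", "neighbourhood_deprivation", "alcohol_use_disorder", "drug_use_disorder", "any_mental_disorder"],
  "betas": {
    "gender": {"female": -0.3},
    "age_at_release": -0.02,
    "immigrant_status": {"yes": 0.1},
    "incarceration_length": {"6-12m": 0.1, "12-24m": 0.2, ">=24m": 0.3},
    "violent_index_offence": {"yes": 0.3},
    "previous_violent_crime": {"yes": 0.5},
    "civil_status": {"other": -0.2},
    "education": {"9-11y": -0.1838, ">=12y": -0.4282},
    "employment": {"yes": -0.3},
    "disposable_income": {"zero": 0.5251, "low": 0.5176, "medium": 0.3712, "high": 0.4509},
    "neighbourhood_deprivation": 0.2,
    "alcohol_use_disorder": {"yes": 0.4},
    "drug_use_disorder": {"yes": 0.4},
    "any_mental_disorder": {"yes": 0.2},
    "any_severe_mental_disorder": {"yes": 0.0953}
  },
  "reference_levels": {
    "gender": "male",
    "immigrant_status": "no",
    "incarceration_length": "<6m",
    "violent_index_offence": "no",
    "previous_violent_crime": "no",
    "civil_status": "unmarried",
    "education": "<9y",
    "employment": "no",
    "disposable_income": "negative",
    "alcohol_use_disorder": "no",
    "drug_use_disorder": "no",
    "any_mental_disorder": "no",
    "any_severe_mental_disorder": "no"
  },
  "absent_prevalences": {
    "education": {"9-11y": 0.4263, ">=12y": 0.0569},
    "disposable_income": {"zero": 0.0523, "low": 0.4903, "medium": 0.3738, "high": 0.0109},
    "any_severe_mental_disorder": {"yes": 0.0347}
  },
  "baseline_survival": {"12": 0.4643, "24": 0.3509},
  "recalibration_slopes": {"12": 0.6745, "24": 0.5372},
  "category_cutoffs": [0.3, 0.6]
}
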