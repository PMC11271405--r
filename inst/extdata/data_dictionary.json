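{
  "format": "Four UTF-8 CSV tables with mandatory header row. Missing values are empty fields. All *_day columns are integer day offsets from study start (4 weeks = 28, 24 weeks = 168, 2 years = 730 days).",
  "patients.csv": {
    "patient_id": "opaque string key, unique",
    "diagnosis_group": "CNS | SOLID | HM",
    "enrollment_day": "integer; <= mtb_day",
    "enrollment_status": "DIAGNOSIS | FIRST_RELAPSE | GE2_RELAPSE",
    "mtb_day": "integer day of molecular-tumor-board discussion; <= last_followup_day",
    "death_day": "optional integer; when present must equal last_followup_day",
    "last_followup_day": "integer",
    "progression_days": "semicolon-separated strictly increasing integer days of disease progression since enrollment; empty for none"
  },
  "recommendations.csv": {
    "recommendation_id": "opaque string key, unique",
    "patient_id": "foreign key to patients",
    "tier": "T1 | T2 | T3 | T4 | T5 (strength of evidence, T1 strongest)",
    "target_gene": "string",
    "aberration_class": "FUSION_SV | SNV | CNV | HIGH_RNA_ONLY | OTHER",
    "therapy_type": "TARGETED_MONO | TARGETED_DUAL | TARGETED_PLUS_CHEMO | CHEMO"
  },
  "courses.csv": {
    "course_id": "opaque string key, unique",
    "patient_id": "foreign key to patients",
    "category": "PGT | UGT | SOC | OTHER",
    "recommendation_id": "foreign key to recommendations; required iff category == PGT",
    "start_day": "integer; < stop_day; >= patient mtb_day unless pre_mtb",
    "stop_day": "integer",
    "baseline_state": "MEASURABLE | NONMEASURABLE_EVALUABLE | NED",
    "n_progressions_before_start": "integer >= 0",
    "modality": "RECIST | RANO | PERCIST | LEUKEMIA",
    "pre_mtb": "TRUE when the course deliberately started before the MTB discussion"
  },
  "assessments.csv": {
    "course_id": "foreign key to courses",
    "day": "integer; >= course start_day; the earliest row per course is the baseline",
    "target_sum": "optional non-negative real; mm diameter sum (or SUV-derived quantity for PERCIST); required at baseline for MEASURABLE imaging courses",
    "nonmeasurable_status": "optional DISAPPEARED | PERSISTS | UNEQUIVOCAL_PROGRESSION",
    "new_lesions": "boolean",
    "marrow_blast_pct": "optional real in [0,100]; required for LEUKEMIA courses",
    "circulating_blast_abs": "optional non-negative real (cells per microliter)",
    "extramedullary": "optional boolean"
  }
}
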