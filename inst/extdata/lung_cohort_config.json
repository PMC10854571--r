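{
  "horizon": 36,
  "covariates": [
    {"name": "age", "kind": "continuous"},
    {"name": "race", "kind": "categorical",
     "levels": ["American Indian", "Asian", "Black", "White"],
     "reference": "American Indian"},
    {"name": "gender", "kind": "categorical",
     "levels": ["Male", "Female"], "reference": "Male"},
    {"name": "treatment", "kind": "categorical",
     "levels": ["No Treatment", "Monotherapy", "Bimodal Therapy",
                "Trimodal Therapy"],
     "reference": "No Treatment"},
    {"name": "histology", "kind": "categorical",
     "levels": ["Epithelial Neoplasms", "Squamous Cell Neoplasms",
                "Adenomas and Adenocarcinomas", "Others"],
     "reference": "Epithelial Neoplasms"},
    {"name": "primary_site", "kind": "categorical",
     "levels": ["Main Bronchus", "Upper Lobe", "Middle Lobe", "Lower Lobe",
                "Lung NOS", "Overlapping Lesion of Lung"],
     "reference": "Main Bronchus"},
    {"name": "grade", "kind": "categorical",
     "levels": ["Well-Differentiated", "Moderately Differentiated",
                "Poorly Differentiated", "Undifferentiated"],
     "reference": "Well-Differentiated"},
    {"name": "tisp", "kind": "continuous"},
    {"name": "metastases", "kind": "categorical",
     "levels": ["Bone Only", "Bone and Brain", "Brain Only"],
     "reference": "Bone Only"}
  ]
}
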