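icd10,phecode,phenotype_label,category
K76.0,571.5,Other chronic nonalcoholic liver disease,digestive
K74.6,571.5,Other chronic nonalcoholic liver disease,digestive
E11,250.2,Type 2 diabetes,endocrine/metabolic
E10,250.1,Type 1 diabetes,endocrine/metabolic
I10,401.1,Essential hypertension,circulatory system
N17,585,Renal failure,genitourinary
N18,585,Renal failure,genitourinary
N19,585,Renal failure,genitourinary
N00,580,Acute glomerulonephritis,genitourinary
J18,480,Pneumonia,respiratory
G20,332,Parkinson's disease,neurological
G25,333,Extrapyramidal disease and abnormal movement disorders,neurological
F41,300.1,Anxiety disorders,mental disorders
G47,327,Sleep disorders,neurological
E78,272.1,Disorders of lipid metabolism,endocrine/metabolic
K57,562.1,Diverticulosis,digestive
M15,740,Osteoarthrosis,musculoskeletal
M16,740,Osteoarthrosis,musculoskeletal
M17,740,Osteoarthrosis,musculoskeletal
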