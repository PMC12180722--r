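"pt","soc_name","soc_code"
"Myelosuppression","Blood and lymphatic system disorders",10005329
"Granulocyte count decreased","Investigations",10022891
"Immune-mediated hepatic disorder","Hepatobiliary disorders",10019805
"Immune-mediated myocarditis","Cardiac disorders",10007541
"Bicytopenia","Blood and lymphatic system disorders",10005329
"White blood cell count decreased","Investigations",10022891
"Neutrophil count decreased","Investigations",10022891
"Papule","Skin and subcutaneous tissue disorders",10040785
"Liver injury","Hepatobiliary disorders",10019805
"Off label use","Injury, poisoning and procedural complications",10022117
"Myocarditis","Cardiac disorders",10007541
"Adrenal insufficiency","Endocrine disorders",10014698
"Electrolyte imbalance","Metabolism and nutrition disorders",10027433
"Hypothyroidism","Endocrine disorders",10014698
"Mouth ulceration","Gastrointestinal disorders",10017947
"Drug eruption","Skin and subcutaneous tissue disorders",10040785
"Hepatic function abnormal","Hepatobiliary disorders",10019805
"Platelet count decreased","Investigations",10022891
"Full blood count decreased","Investigations",10022891
"Drug-induced liver injury","Hepatobiliary disorders",10019805
"Rash erythematous","Skin and subcutaneous tissue disorders",10040785
"Medication error","Injury, poisoning and procedural complications",10022117
"Interstitial lung disease","Respiratory, thoracic and mediastinal disorders",10038738
"PT_001","Injury, poisoning and procedural complications",10022117
"PT_002","Investigations",10022891
"PT_003","Blood and lymphatic system disorders",10005329
"PT_004","Gastrointestinal disorders",10017947
"PT_005","Skin and subcutaneous tissue disorders",10040785
"PT_006","Hepatobiliary disorders",10019805
"PT_007","General disorders and administration site conditions",10018065
"PT_008","Renal and urinary disorders",10038359
"PT_009","Respiratory, thoracic and mediastinal disorders",10038738
"PT_010","Metabolism and nutrition disorders",10027433
"PT_011","Cardiac disorders",10007541
"PT_012","Infections and infestations",10021881
"PT_013","Endocrine disorders",10014698
"PT_014","Nervous system disorders",10029205
"PT_015","Musculoskeletal and connective tissue disorders",10028395
"PT_016","Vascular disorders",10047065
"PT_017","Eye disorders",10015919
"PT_018","Immune system disorders",10021428
"PT_019","Ear and labyrinth disorders",10013993
"PT_020","Congenital, familial and genetic disorders",10010331
"PT_021","Injury, poisoning and procedural complications",10022117
"PT_022","Investigations",10022891
"PT_023","Blood and lymphatic system disorders",10005329
"PT_024","Gastrointestinal disorders",10017947
"PT_025","Skin and subcutaneous tissue disorders",10040785
"PT_026","Hepatobiliary disorders",10019805
"PT_027","General disorders and administration site conditions",10018065
"PT_028","Renal and urinary disorders",10038359
"PT_029","Respiratory, thoracic and mediastinal disorders",10038738
"PT_030","Metabolism and nutrition disorders",10027433
"PT_031","Cardiac disorders",10007541
"PT_032","Infections and infestations",10021881
"PT_033","Endocrine disorders",10014698
"PT_034","Nervous system disorders",10029205
"PT_035","Musculoskeletal and connective tissue disorders",10028395
"PT_036","Vascular disorders",10047065
"PT_037","Eye disorders",10015919
"PT_038","Immune system disorders",10021428
"PT_039","Ear and labyrinth disorders",10013993
"PT_040","Congenital, familial and genetic disorders",10010331
"PT_041","Injury, poisoning and procedural complications",10022117
"PT_042","Investigations",10022891
"PT_043","Blood and lymphatic system disorders",10005329
"PT_044","Gastrointestinal disorders",10017947
"PT_045","Skin and subcutaneous tissue disorders",10040785
"PT_046","Hepatobiliary disorders",10019805
"PT_047","General disorders and administration site conditions",10018065
"PT_048","Renal and urinary disorders",10038359
"PT_049","Respiratory, thoracic and mediastinal disorders",10038738
"PT_050","Metabolism and nutrition disorders",10027433
"PT_051","Cardiac disorders",10007541
"PT_052","Infections and infestations",10021881
"PT_053","Endocrine disorders",10014698
"PT_054","Nervous system disorders",10029205
"PT_055","Musculoskeletal and connective tissue disorders",10028395
"PT_056","Vascular disorders",10047065
"PT_057","Eye disorders",10015919
"PT_058","Immune system disorders",10021428
"PT_059","Ear and labyrinth disorders",10013993
"PT_060","Congenital, familial and genetic disorders",10010331
"PT_061","Injury, poisoning and procedural complications",10022117
"PT_062","Investigations",10022891
"PT_063","Blood and lymphatic system disorders",10005329
"PT_064","Gastrointestinal disorders",10017947
"PT_065","Skin and subcutaneous tissue disorders",10040785
"PT_066","Hepatobiliary disorders",10019805
"PT_067","General disorders and administration site conditions",10018065
"PT_068","Renal and urinary disorders",10038359
"PT_069","Respiratory, thoracic and mediastinal disorders",10038738
"PT_070","Metabolism and nutrition disorders",10027433
"PT_071","Cardiac disorders",10007541
"PT_072","Infections and infestations",10021881
"PT_073","Endocrine disorders",10014698
"PT_074","Nervous system disorders",10029205
"PT_075","Musculoskeletal and connective tissue disorders",10028395
"PT_076","Vascular disorders",10047065
"PT_077","Eye disorders",10015919
"PT_078","Immune system disorders",10021428
"PT_079","Ear and labyrinth disorders",10013993
"PT_080","Congenital, familial and genetic disorders",10010331
"PT_081","Injury, poisoning and procedural complications",10022117
"PT_082","Investigations",10022891
"PT_083","Blood and lymphatic system disorders",10005329
"PT_084","Gastrointestinal disorders",10017947
"PT_085","Skin and subcutaneous tissue disorders",10040785
"PT_086","Hepatobiliary disorders",10019805
"PT_087","General disorders and administration site conditions",10018065
"PT_088","Renal and urinary disorders",10038359
"PT_089","Respiratory, thoracic and mediastinal disorders",10038738
"PT_090","Metabolism and nutrition disorders",10027433
"PT_091","Cardiac disorders",10007541
"PT_092","Infections and infestations",10021881
"PT_093","Endocrine disorders",10014698
"PT_094","Nervous system disorders",10029205
"PT_095","Musculoskeletal and connective tissue disorders",10028395
"PT_096","Vascular disorders",10047065
"PT_097","Eye disorders",10015919
"PT_098","Immune system disorders",10021428
"PT_099","Ear and labyrinth disorders",10013993
"PT_100","Congenital, familial and genetic disorders",10010331
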