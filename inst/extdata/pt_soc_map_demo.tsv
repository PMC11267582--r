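pt	soc
Nasopharyngitis	Infections and infestations
Upper respiratory tract infection	Infections and infestations
Urinary tract infection	Infections and infestations
Pneumonia	Infections and infestations
Bronchitis	Infections and infestations
Cellulitis	Infections and infestations
Sinusitis	Infections and infestations
Herpes zoster	Infections and infestations
Vulvovaginal candidiasis	Infections and infestations
Tuberculosis	Infections and infestations
Herpes simplex	Infections and infestations
Coronavirus infection	Infections and infestations
Diverticulitis	Infections and infestations
Psoriasis	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Urticaria	Skin and subcutaneous tissue disorders
Erythema	Skin and subcutaneous tissue disorders
Alopecia	Skin and subcutaneous tissue disorders
Drug ineffective	General disorders and administration site conditions
Condition aggravated	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Injection site pain	General disorders and administration site conditions
Injection site urticaria	General disorders and administration site conditions
Therapeutic response decreased	General disorders and administration site conditions
Disease recurrence	General disorders and administration site conditions
Therapy non-responder	General disorders and administration site conditions
Nausea	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Migraine	Nervous system disorders
Paraesthesia	Nervous system disorders
Atrial fibrillation	Cardiac disorders
Myocardial infarction	Cardiac disorders
Palpitations	Cardiac disorders
Aortic valve incompetence	Cardiac disorders
Therapy cessation	Surgical and medical procedures
Therapy interrupted	Surgical and medical procedures
Exposure during pregnancy	Injury, poisoning and procedural complications
Fall	Injury, poisoning and procedural complications
Contusion	Injury, poisoning and procedural complications
Meniscus injury	Injury, poisoning and procedural complications
Arthralgia	Musculoskeletal and connective tissue disorders
Back pain	Musculoskeletal and connective tissue disorders
Myalgia	Musculoskeletal and connective tissue disorders
Cough	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders
Insomnia	Psychiatric disorders
Anxiety	Psychiatric disorders
Depression	Psychiatric disorders
Weight increased	Investigations
Blood pressure increased	Investigations
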