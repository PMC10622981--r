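pt_code,pt_name,hlt,hlgt,soc,smqs,disease_flag,dsm5_domain
memory_impairment,Memory impairment,memory loss symptoms,mental impairment disorders,nervous system disorders,dementia,FALSE,learning and memory
amnesia,Amnesia,memory loss symptoms,mental impairment disorders,nervous system disorders,dementia,FALSE,learning and memory
cognitive_disorder,Cognitive disorder,cognitive disturbances,mental impairment disorders,nervous system disorders,dementia,FALSE,complex attention
mental_impairment,Mental impairment,cognitive disturbances,mental impairment disorders,nervous system disorders,,FALSE,complex attention
dementia,Dementia,dementias,mental impairment disorders,nervous system disorders,dementia,TRUE,
dementia_alzheimers_type,Dementia Alzheimer's type,dementias,mental impairment disorders,nervous system disorders,dementia,TRUE,
disturbance_in_attention,Disturbance in attention,attention disturbances,cognitive and attention disorders and disturbances,nervous system disorders,dementia,FALSE,complex attention
bradyphrenia,Bradyphrenia,cognitive slowing,cognitive and attention disorders and disturbances,nervous system disorders,,FALSE,executive function
executive_dysfunction,Executive dysfunction,cognitive slowing,cognitive and attention disorders and disturbances,nervous system disorders,,FALSE,executive function
aphasia,Aphasia,speech and language disturbances,cognitive and attention disorders and disturbances,nervous system disorders,dementia,FALSE,language
speech_disorder,Speech disorder,speech and language disturbances,cognitive and attention disorders and disturbances,nervous system disorders,,FALSE,language
dysarthria,Dysarthria,speech and language disturbances,cognitive and attention disorders and disturbances,nervous system disorders,,FALSE,language
apraxia,Apraxia,higher motor disturbances,cognitive and attention disorders and disturbances,nervous system disorders,dementia,FALSE,perceptual motor function
agnosia,Agnosia,higher motor disturbances,cognitive and attention disorders and disturbances,nervous system disorders,,FALSE,perceptual motor function
mild_cognitive_impairment,Mild cognitive impairment,cognitive disturbances,cognitive and attention disorders and disturbances,nervous system disorders,dementia,TRUE,
confusional_state,Confusional state,confusion symptoms,deliria,psychiatric disorders,dementia,FALSE,complex attention
disorientation,Disorientation,confusion symptoms,deliria,psychiatric disorders,,FALSE,complex attention
delirium,Delirium,deliria conditions,deliria,psychiatric disorders,,TRUE,
retrograde_amnesia,Retrograde amnesia,amnestic symptoms,dementia and amnestic condition,psychiatric disorders,dementia,FALSE,learning and memory
anterograde_amnesia,Anterograde amnesia,amnestic symptoms,dementia and amnestic condition,psychiatric disorders,,FALSE,learning and memory
transient_global_amnesia,Transient global amnesia,amnestic conditions,dementia and amnestic condition,psychiatric disorders,,TRUE,
thinking_abnormal,Thinking abnormal,thinking disturbances,disturbances in thinking and perception,psychiatric disorders,,FALSE,executive function
hallucination,Hallucination,perception disturbances,disturbances in thinking and perception,psychiatric disorders,,FALSE,perceptual motor function
illusion,Illusion,perception disturbances,disturbances in thinking and perception,psychiatric disorders,,FALSE,perceptual motor function
inappropriate_affect,Inappropriate affect,behavioural disturbances,disturbances in thinking and perception,psychiatric disorders,,FALSE,social cognition
social_avoidant_behaviour,Social avoidant behaviour,behavioural disturbances,disturbances in thinking and perception,psychiatric disorders,,FALSE,social cognition
disinhibition,Disinhibition,behavioural disturbances,disturbances in thinking and perception,psychiatric disorders,,FALSE,social cognition
delusional_disorder,Delusional disorder,thinking conditions,disturbances in thinking and perception,psychiatric disorders,,TRUE,
nausea,Nausea,nausea and vomiting symptoms,gastrointestinal motility and defaecation conditions,gastrointestinal disorders,,FALSE,
vomiting,Vomiting,nausea and vomiting symptoms,gastrointestinal motility and defaecation conditions,gastrointestinal disorders,,FALSE,
diarrhoea,Diarrhoea,diarrhoea symptoms,gastrointestinal motility and defaecation conditions,gastrointestinal disorders,,FALSE,
fatigue,Fatigue,asthenic conditions,general system disorders,general disorders,,FALSE,
asthenia,Asthenia,asthenic conditions,general system disorders,general disorders,,FALSE,
pyrexia,Pyrexia,febrile disorders,general system disorders,general disorders,,FALSE,
arthralgia,Arthralgia,joint related symptoms,joint disorders,musculoskeletal disorders,,FALSE,
myalgia,Myalgia,muscle pains,muscle disorders,musculoskeletal disorders,,FALSE,
back_pain,Back pain,musculoskeletal pain,muscle disorders,musculoskeletal disorders,,FALSE,
hot_flush,Hot flush,vascular symptoms,vascular disorders nec,vascular disorders,,FALSE,
hypertension,Hypertension,vascular hypertensive disorders,vascular disorders nec,vascular disorders,,FALSE,
neutropenia,Neutropenia,neutropenias,white blood cell disorders,blood and lymphatic system disorders,,FALSE,
anaemia,Anaemia,anaemias nec,red blood cell disorders,blood and lymphatic system disorders,,FALSE,
thrombocytopenia,Thrombocytopenia,thrombocytopenias,platelet disorders,blood and lymphatic system disorders,,FALSE,
alopecia,Alopecia,alopecias,epidermal conditions,skin and subcutaneous tissue disorders,,FALSE,
rash,Rash,rashes eruptions and exanthems,epidermal conditions,skin and subcutaneous tissue disorders,,FALSE,
headache,Headache,headaches nec,headaches,nervous system disorders,,FALSE,
dizziness,Dizziness,neurological signs nec,neurological disorders nec,nervous system disorders,,FALSE,
insomnia,Insomnia,sleep disturbances,sleep disorders and disturbances,psychiatric disorders,,FALSE,
depression,Depression,depressive disorders,mood disorders and disturbances,psychiatric disorders,,FALSE,
anxiety,Anxiety,anxiety symptoms,anxiety disorders and symptoms,psychiatric disorders,,FALSE,
decreased_appetite,Decreased appetite,appetite disorders,appetite and general nutrition disorders,metabolism and nutrition disorders,,FALSE,
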