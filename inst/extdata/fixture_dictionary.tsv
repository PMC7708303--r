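source_code	icd_code	hpo_id
Absence seizure	G40.A09	HP:0002121
Childhood absence epilepsy	G40.A09	HP:0002121
Atypical absence seizure	G40.A19	HP:0002121
Generalized convulsive epilepsy	G40.409	HP:0002197
Generalized idiopathic epilepsy	G40.309	HP:0002197
Generalized tonic-clonic seizure	G40.409	HP:0002197
Focal epilepsy	G40.209	HP:0007359
Focal seizure with impaired awareness	G40.209	HP:0007359
Localization-related epilepsy	G40.109	HP:0007359
Myoclonic seizure	G40.409	HP:0002123
Juvenile myoclonic epilepsy	G40.B09	HP:0002123
Status epilepticus	G40.901	HP:0002133
Convulsive status epilepticus	G40.901	HP:0002133
Infantile spasms	G40.822	HP:0012469
West syndrome	G40.822	HP:0012469
Epileptic spasms	G40.822	HP:0011097
Febrile convulsion	R56.00	HP:0002373
Complex febrile seizure	R56.01	HP:0002373
Seizure disorder	R56.9	HP:0001250
Convulsions	R56.9	HP:0001250
Epilepsy unspecified	G40.909	HP:0001250
Recurrent seizures	G40.909	HP:0001250
Intellectual disability	F79	HP:0001249
Global developmental delay with intellectual disability	F73	HP:0001249
Severe intellectual disability	F72	HP:0010864
Profound intellectual disability	F73	HP:0010864
Attention deficit hyperactivity disorder	F90.0	HP:0007018
ADHD combined type	F90.2	HP:0007018
Speech delay	F80.9	HP:0002167
Expressive language disorder	F80.1	HP:0002167
Hypotonia	P94.2	HP:0001252
Congenital hypotonia	P94.2	HP:0001290
Benign congenital hypotonia	P94.2	HP:0001290
Muscular hypotonia of infancy	P94.2	HP:0001290
Developmental delay	F88	HP:0001263
Neurodevelopmental disorder	F88	HP:0012759
Global developmental delay	F88	HP:0001263
Delayed milestones	R62.0	HP:0002194
Ataxia	R27.0	HP:0001251
Chorea	G25.5	HP:0002072
Dystonia	G24.9	HP:0001332
Rigidity	G25.89	HP:0002063
Spasticity	G80.1	HP:0001257
Cerebral palsy	G80.9	HP:0001257
Hypertonia	P94.1	HP:0001276
Microcephaly	Q02	HP:0000252
Hydrocephalus	Q03.9	HP:0002119
Agenesis of corpus callosum	Q04.0	HP:0001274
Polymicrogyria	Q04.3	HP:0002126
Headache	R51	HP:0002315
Migraine	G43.909	HP:0002076
Sleep disorder	G47.9	HP:0002360
Obstructive sleep apnea	G47.33	HP:0010535
Encephalopathy	G93.40	HP:0001298
Autism spectrum disorder	F84.0	HP:0000717
Anxiety disorder	F41.9	HP:0000739
Depressive disorder	F32.9	HP:0000716
Abnormal EEG	R94.01
Encephalopathy follow-up	G93.40
Neurology follow-up visit	R62.50
Asthma	J45.40
Well child visit	Z00.129
Acute otitis media	H66.90
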