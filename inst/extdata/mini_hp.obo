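format-version: 1.2
data-version: mini/2026-01
ontology: mini-hp

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000118
name: Phenotypic abnormality
is_a: HP:0000001 ! All

[Term]
id: HP:0000707
name: Abnormality of the nervous system
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0012638
name: Abnormal nervous system physiology
is_a: HP:0000707 ! Abnormality of the nervous system

[Term]
id: HP:0001250
name: Seizure
alt_id: HP:0002279
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0002197
name: Generalized-onset seizure
is_a: HP:0001250 ! Seizure

[Term]
id: HP:0020219
name: Motor seizure
is_a: HP:0001250 ! Seizure

[Term]
id: HP:0007359
name: Focal-onset seizure
is_a: HP:0001250 ! Seizure

[Term]
id: HP:0002121
name: Absence seizure
is_a: HP:0002197 ! Generalized-onset seizure

[Term]
id: HP:0002123
name: Generalized myoclonic seizure
is_a: HP:0002197 ! Generalized-onset seizure
is_a: HP:0020219 ! Motor seizure

[Term]
id: HP:0011097
name: Epileptic spasm
is_a: HP:0020219 ! Motor seizure

[Term]
id: HP:0012469
name: Infantile spasms
is_a: HP:0011097 ! Epileptic spasm

[Term]
id: HP:0002133
name: Status epilepticus
is_a: HP:0001250 ! Seizure

[Term]
id: HP:0002373
name: Febrile seizure (within the age range of 3 months to 6 years)
is_a: HP:0001250 ! Seizure

[Term]
id: HP:0012759
name: Neurodevelopmental abnormality
is_a: HP:0000707 ! Abnormality of the nervous system

[Term]
id: HP:0001249
name: Intellectual disability
is_a: HP:0012759 ! Neurodevelopmental abnormality

[Term]
id: HP:0010864
name: Intellectual disability, severe
is_a: HP:0001249 ! Intellectual disability

[Term]
id: HP:0007018
name: Attention deficit hyperactivity disorder
is_a: HP:0012759 ! Neurodevelopmental abnormality

[Term]
id: HP:0002167
name: Neurological speech impairment
is_a: HP:0012759 ! Neurodevelopmental abnormality

[Term]
id: HP:0001252
name: Hypotonia
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0001290
name: Generalized hypotonia
is_a: HP:0001252 ! Hypotonia

[Term]
id: HP:0100022
name: Abnormality of movement
is_a: HP:0000707 ! Abnormality of the nervous system

[Term]
id: HP:0001251
name: Ataxia
is_a: HP:0100022 ! Abnormality of movement

[Term]
id: HP:0002072
name: Chorea
is_a: HP:0100022 ! Abnormality of movement

[Term]
id: HP:0001332
name: Dystonia
is_a: HP:0100022 ! Abnormality of movement

[Term]
id: HP:0002063
name: Rigidity
is_a: HP:0100022 ! Abnormality of movement

[Term]
id: HP:0003808
name: Abnormal muscle tone
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0001276
name: Hypertonia
is_a: HP:0003808 ! Abnormal muscle tone

[Term]
id: HP:0001257
name: Spasticity
is_a: HP:0001276 ! Hypertonia
is_a: HP:0100022 ! Abnormality of movement

[Term]
id: HP:0012443
name: Abnormality of brain morphology
is_a: HP:0000707 ! Abnormality of the nervous system

[Term]
id: HP:0000252
name: Microcephaly
is_a: HP:0012443 ! Abnormality of brain morphology

[Term]
id: HP:0002119
name: Ventriculomegaly
is_a: HP:0012443 ! Abnormality of brain morphology

[Term]
id: HP:0001274
name: Agenesis of corpus callosum
is_a: HP:0012443 ! Abnormality of brain morphology

[Term]
id: HP:0002126
name: Polymicrogyria
is_a: HP:0012443 ! Abnormality of brain morphology

[Term]
id: HP:0002315
name: Headache
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0002076
name: Migraine
is_a: HP:0002315 ! Headache

[Term]
id: HP:0002360
name: Sleep abnormality
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0010535
name: Sleep apnea
is_a: HP:0002360 ! Sleep abnormality

[Term]
id: HP:0001298
name: Encephalopathy
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0000708
name: Behavioral abnormality
is_a: HP:0000707 ! Abnormality of the nervous system

[Term]
id: HP:0000717
name: Autism
is_a: HP:0000708 ! Behavioral abnormality

[Term]
id: HP:0000739
name: Anxiety
is_a: HP:0000708 ! Behavioral abnormality

[Term]
id: HP:0000716
name: Depression
is_a: HP:0000708 ! Behavioral abnormality

[Term]
id: HP:0001263
name: Global developmental delay
is_a: HP:0012759 ! Neurodevelopmental abnormality

[Term]
id: HP:0002194
name: Delayed gross motor development
is_a: HP:0001263 ! Global developmental delay

[Term]
id: HP:0012823
name: Clinical modifier
is_a: HP:0000001 ! All

[Term]
id: HP:0012824
name: Severity
is_a: HP:0012823 ! Clinical modifier

[Term]
id: HP:0031797
name: Clinical course
is_a: HP:0000001 ! All

[Term]
id: HP:0003674
name: Onset
is_a: HP:0031797 ! Clinical course

[Term]
id: HP:0003593
name: Infantile onset
is_a: HP:0003674 ! Onset

[Term]
id: HP:0009999
name: obsolete Seizure equivalent
is_obsolete: true
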