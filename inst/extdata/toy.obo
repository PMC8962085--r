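format-version: 1.2
ontology: toy-phenotype

[Term]
id: HP:0000001
name: Phenotypic abnormality

[Term]
id: HP:0000002
name: Abnormality of branch A
is_a: HP:0000001 ! Phenotypic abnormality

[Term]
id: HP:0000003
name: Abnormality of branch B
is_a: HP:0000001 ! Phenotypic abnormality

[Term]
id: HP:0000004
name: Leaf A1
is_a: HP:0000002 ! Abnormality of branch A

[Term]
id: HP:0000005
name: Leaf A2
is_a: HP:0000002 ! Abnormality of branch A
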