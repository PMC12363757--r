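sample_id	stratum	aao_years	sex
P1	PROTECTED	NA	1
P2	PROTECTED	NA	0
M1	CASE_MUTANT	55	1
M2	CASE_MUTANT	62	0
I1	CASE_IDIOPATHIC	58	1
C1	CONTROL	NA	0
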