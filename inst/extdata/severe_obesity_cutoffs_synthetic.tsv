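sex	age	bmi_cutoff
male	4	21.2
male	5	21.54
male	6	22.04
male	7	22.72
male	8	23.56
male	9	24.58
male	10	25.76
male	11	27.11
male	12	28.64
male	13	30.34
female	4	21.5
female	5	21.84
female	6	22.34
female	7	23.02
female	8	23.86
female	9	24.88
female	10	26.06
female	11	27.41
female	12	28.94
female	13	30.64
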