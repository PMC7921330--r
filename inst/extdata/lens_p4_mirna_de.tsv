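feature	mean_case	mean_control	fc	p
mmu-mir-1198	18.3	30.6	-1.7	0.024
mmu-mir-382	16.6	28.6	-1.7	0.044
mmu-mir-1947	30.6	45.1	-1.5	0.048
mmu-mir-409	62.5	80.6	-1.4	0.019
mmu-mir-3092	14.5	20.1	-1.4	0.021
mmu-let-7b	483.7	627.0	-1.3	0.031
mmu-mir-298	77.9	99.5	-1.3	0.022
mmu-mir-34c	102.5	120.5	-1.2	0.044
mmu-mir-3107	92.4	75.7	1.2	0.049
mmu-mir-378b	27.6	21.3	1.3	0.046
mmu-mir-339	27.3	20.4	1.4	0.031
mmu-mir-384	7.4	5.2	1.4	0.018
mmu-mir-138	9.8	6.5	1.5	0.042
mmu-mir-1224	18.5	12.2	1.5	0.006
mmu-mir-1935	11.0	7.0	1.6	0.018
mmu-mir-328	25.2	16.4	1.6	0.024
mmu-mir-3102	20.0	12.5	1.6	0.008
mmu-mir-19a	13.0	8.2	1.7	0.049
mmu-mir-345	8.2	4.4	1.8	0.027
mmu-mir-1946a	14.5	7.4	1.9	0.035
mmu-mir-467a	15.3	7.5	2.1	0.010
mmu-mir-15a	15.8	7.2	2.2	0.012
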