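offspring_id	parent1_id	parent1_lod	parent1_sig	parent1_maternal	parent2_id	parent2_lod	parent2_sig	parent2_maternal	pair_lod	pair_sig
pop1_102	pop1_100	8.56e15	TRUE	TRUE	pop1_086	4.19e15	TRUE	FALSE	1.79e16	TRUE
pop1_113	pop1_111	8.15e15	TRUE	TRUE	pop1_114	8.86e15	TRUE	FALSE	2.16e16	TRUE
pop1_012	pop1_001	3.41e15	TRUE	FALSE	pop1_008	2.40e15	TRUE	TRUE	8.37e15	TRUE
pop1_025	pop1_001	3.21e15	TRUE	FALSE	pop1_026	5.42e14	TRUE	TRUE	5.90e15	TRUE
pop1_027	pop1_024	-1.84e16	FALSE	FALSE	pop1_026	6.42e15	TRUE	TRUE	0	FALSE
pop1_028	pop1_026	7.49e15	TRUE	TRUE	pop1_026	7.49e15	TRUE	TRUE	1.42e16	TRUE
pop1_032	pop1_026	2.50e15	TRUE	FALSE	pop1_037	2.16e15	TRUE	TRUE	5.54e15	TRUE
pop1_034	pop1_037	4.23e15	TRUE	TRUE	pop1_037	4.23e15	TRUE	TRUE	8.23e15	TRUE
pop1_035	pop1_037	4.52e15	TRUE	TRUE	pop1_037	4.52e15	TRUE	TRUE	8.30e15	TRUE
pop1_036	pop1_037	4.60e15	TRUE	TRUE	pop1_037	4.60e15	TRUE	TRUE	5.51e15	TRUE
pop1_038	pop1_037	4.49e15	TRUE	TRUE	pop1_037	4.49e15	TRUE	TRUE	8.18e15	TRUE
pop1_039	pop1_001	7.58e15	TRUE	TRUE	pop1_001	7.58e15	TRUE	TRUE	1.46e16	TRUE
pop1_055	pop1_004	-1.83e16	FALSE	FALSE	pop1_082	2.00e16	TRUE	TRUE	0	FALSE
pop1_059	pop1_037	2.20e16	TRUE	TRUE	pop1_004	-2.12e16	FALSE	FALSE	0	FALSE
pop1_085	pop1_083	-8.31e15	FALSE	FALSE	pop1_086	1.98e16	TRUE	TRUE	0	FALSE
pop1_087	pop1_037	-5.04e15	FALSE	FALSE	pop1_086	2.51e15	TRUE	TRUE	0	FALSE
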