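cohort	f	f1	se	sp	nb	sigma_m	d_census	ne_ratio
seedlings	0.071	0.1553	0.0032	0.0651	15.37	156.40	0.37	0.30
adults	-0.034	0.0306	0.0012	0.0208	48.07	276.90	0.79	0.30
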