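quantity	set	numerator	denominator	printed_pct	digits
alignment_coverage	all_aligned	571365933	1081644591	52.8	1
ce_pct_of_alignment	all_branch_CE	50570632	571258887	8.85	2
ncrna_pct	all_aligned	269314	9655872	2.79	2
ncrna_pct	all_branch_CE	23644	842688	2.81	2
ncrna_pct	AR_A_allogus	4134	121461	3.40	2
ncrna_pct	AR_A_homolechis	4710	132887	3.54	2
ncrna_pct	AR_A_sagrei	4980	143540	3.47	2
ncrna_pct	AR_A_isolepis	2005	52357	3.83	2
ncrna_pct	AR_A_allisoni	1981	53312	3.72	2
ncrna_pct	AR_A_porcatus	2235	61666	3.62	2
ncrna_pct	AR_A_carolinensis	1021	32880	3.11	2
ncrna_pct	AR_TC_open	398	12395	3.21	2
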