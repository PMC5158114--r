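# Suberin degradation/utilization pathway catalog, transcribed from the source table.
# detection: both = detected at both sampling times; late_only = only at the
# late sampling (day 30 R. thiooxydans / day 25 M. xanthus); day5_only = only day 5.
# Q1D5V0 is printed with a letter O in the source table; normalized here to match
# the M. xanthus protein list.
organism	process	step	accession	detection
Rhodanobacter thiooxydans	suberin_adhesion	.	I4WDW1	both
Myxococcus xanthus	suberin_adhesion	.	Q1D009	both
Rhodanobacter thiooxydans	depolymerization	.	I4WSC3	both
Rhodanobacter thiooxydans	depolymerization	.	I4WGM2	both
Rhodanobacter thiooxydans	depolymerization	.	I4WUC2	late_only
Myxococcus xanthus	depolymerization	.	Q1CWS1	both
Myxococcus xanthus	depolymerization	.	Q1D4F3	both
Myxococcus xanthus	depolymerization	.	Q1D5W1	day5_only
Myxococcus xanthus	feruloyl_esterase	.	Q1D548	both
Rhodanobacter thiooxydans	lipid_entry	.	I4WU70	both
Myxococcus xanthus	lipid_entry	.	Q1D3Z8	day5_only
Myxococcus xanthus	lipid_entry	.	Q1D5Z6	day5_only
Myxococcus xanthus	lipid_entry	.	Q1DDZ2	day5_only
Rhodanobacter thiooxydans	long_chain_fatty_acid_transport	.	I4WHD4	both
Myxococcus xanthus	long_chain_fatty_acid_transport	.	Q1CWS0	both
Rhodanobacter thiooxydans	coa_activation	.	I4WFP4	both
Rhodanobacter thiooxydans	coa_activation	.	I4WB55	late_only
Myxococcus xanthus	coa_activation	.	Q1D9B8	day5_only
Myxococcus xanthus	coa_activation	.	Q1D855	day5_only
Myxococcus xanthus	coa_activation	.	Q1CYM5	day5_only
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WP46	both
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WSG8	both
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WDA0	both
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WKP8	late_only
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WM94	late_only
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WM95	late_only
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WPU1	late_only
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4WM78	late_only
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	M4NHA9	late_only
Rhodanobacter thiooxydans	beta_oxidation	acyl_coa_dehydrogenase	I4W091	day5_only
Myxococcus xanthus	beta_oxidation	acyl_coa_dehydrogenase	Q1D3D6	both
Myxococcus xanthus	beta_oxidation	acyl_coa_dehydrogenase	Q1D4E4	day5_only
Myxococcus xanthus	beta_oxidation	acyl_coa_dehydrogenase	Q1D5Y1	day5_only
Myxococcus xanthus	beta_oxidation	acyl_coa_dehydrogenase	Q1CZW5	both
Myxococcus xanthus	beta_oxidation	acyl_coa_dehydrogenase	A0A0H4WWQ8	both
Rhodanobacter thiooxydans	beta_oxidation	enoyl_coa_hydratase	I4WR77	day5_only
Rhodanobacter thiooxydans	beta_oxidation	enoyl_coa_hydratase	I4WPL0	both
Myxococcus xanthus	beta_oxidation	enoyl_coa_hydratase	Q1D5U2	day5_only
Rhodanobacter thiooxydans	beta_oxidation	hydroxyacyl_coa_dehydrogenase	I4WIC4	both
Rhodanobacter thiooxydans	beta_oxidation	hydroxyacyl_coa_dehydrogenase	I4VRU7	late_only
Myxococcus xanthus	beta_oxidation	hydroxyacyl_coa_dehydrogenase	Q1D5U1	day5_only
Myxococcus xanthus	beta_oxidation	hydroxyacyl_coa_dehydrogenase	Q1D233	day5_only
Rhodanobacter thiooxydans	beta_oxidation	acetyl_coa_acetyltransferase	I4WBZ6	both
Rhodanobacter thiooxydans	beta_oxidation	acetyl_coa_acetyltransferase	I4WIC3	both
Myxococcus xanthus	beta_oxidation	acetyl_coa_acetyltransferase	Q1D5V0	both
Myxococcus xanthus	beta_oxidation	acetyl_coa_acetyltransferase	Q1D234	day5_only
Myxococcus xanthus	beta_oxidation	acetyl_coa_acetyltransferase	BKT	day5_only
Myxococcus xanthus	beta_oxidation	acetyl_coa_acetyltransferase	Q1D003	late_only
Rhodanobacter thiooxydans	regulation	.	I4WE25	both
Myxococcus xanthus	regulation	.	Q1D964	day5_only
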