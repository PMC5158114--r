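accession	annotation	nspc_day5	nspc_day25	localization	note
Q1CWS1	lipase	0.31	0.21	E	.
Q1D4F3	patatin-like phospholipase	0.35	0.13	I	.
Q1CYB4	acetyl co-enzyme A carboxylase carboxyltransferase	0.37	0.16	E	.
Q1D030	acetyl-coenzyme A synthetase	0.19	0.06	I	.
Q1D5V0	acetyl-CoA acetyltransferase	0.33	0.10	I	.
Q1D9B8	long-chain-fatty-acid-CoA ligase	0.20	—	I	.
Q1D233	3-hydroxyacyl-CoA dehydrogenase	0.17	—	E	.
Q1D5Y2	carboxyl transferase domain protein	0.19	—	I	.
Q1D009	YceI-like family protein	0.27	0.14	E	discussed_outside_lipid_group
Q1D3D6	acyl-CoA dehydrogenase	0.13	0.12	I	.
BKT	beta-ketothiolase	0.17	—	I	.
Q1D5U4	acyl-CoA dehydrogenase	0.10	—	I	.
Q1D984	acetyl-coenzyme A synthetase	0.06	—	I	.
Q1DDA0	propionyl-CoA carboxylase	0.07	0.02	I	.
Q1DFT0	3-oxoacyl-[acyl-carrier protein] reductase	0.21	—	I	.
Q1D0B9	acetyl-CoA carboxylase	0.10	—	I	.
Q1D340	malonyl CoA-acyl carrier protein transacylase	0.11	—	I	.
Q1D5U1	3-hydroxyacyl-CoA dehydrogenase	0.18	—	I	.
Q1D5U2	enoyl CoA dehydratase	0.13	—	I	.
Q1D4E4	acyl-CoA dehydrogenase	0.07	—	I	.
Q1D0T9	acetyl CoA carboxylase	0.03	—	I	.
Q1D555	acetyl-coenzyme A carboxylase carboxyl transferase	0.06	—	I	.
Q1D234	acetyl-CoA acetyltransferase	0.05	—	I	.
Q1CZK4	enoyl-[acyl-carrier-protein] reductase	0.07	—	E	.
Q1DDA2	propionyl-CoA carboxylase	0.04	—	I	.
Q1D343	3-oxoacyl-[acyl-carrier-protein] synthase	0.07	—	E	.
Q1D964	acyl-CoA hydrolase	0.08	—	I	.
Q1CYM5	medium-chain fatty acid-CoA ligase	0.03	—	I	.
Q1D5Y4	3-hydroxybutyryl-CoA dehydratase	0.05	—	I	.
Q1D8V2	acetyl-coenzyme A carboxylase carboxyl transferase	0.05	—	I	.
Q1D5Y1	acyl-CoA dehydrogenase	0.04	—	I	.
Q1D5W1	patatin-like phospholipase	0.01	—	E	.
Q1D5V2	3-oxoacid CoA-transferase	0.07	—	I	.
Q1D855	long-chain-fatty-acid-CoA ligase	0.02	—	I	.
Q1D566	acyltransferase	0.02	—	I	.
Q1CZW5	acyl-CoA dehydrogenase	0.02	0.02	I	.
Q1D003	beta-ketothiolase	0.02	0.13	I	.
A0A0H4WWQ8	acyl-CoA dehydrogenase	0.02	—	I	.
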