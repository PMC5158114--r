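accession	annotation	nspc_day5	nspc_day30	localization
I4VIC2	acyl carrier protein	—	1.44	I
I4VRU7	3-hydroxyacyl-CoA dehydrogenase	—	0.28	I
I4VV45	YdiF, acetate-CoA transferase	—	0.13	I
I4VY74	3-oxoacyl-ACP reductase	—	0.07	I
I4VZY3	acetoacetyl-CoA reductase	—	0.06	E
I4W091	acyl-CoA dehydrogenase domain-containing protein	0.04	—	I
I4WAL3	3-hydroxydecanoyl-[acyl-carrier-protein] dehydratase	—	0.08	E
I4WAL4	beta-ketoacyl-[ACP] synthase I	0.12	0.43	E
I4WAZ2	acetoacetyl-CoA thiolase	0.66	0.66	E
I4WB09	3-hydroxybutyryl-CoA dehydratase	0.13	—	I
I4WB55	long-chain fatty acyl CoA ligase	—	0.07	I
I4WBU8	acetyl-coenzyme A synthetase	0.11	0.12	I
I4WBY7	3-hydroxybutyrate dehydrogenase	—	0.09	E
I4WBZ6	acetyl-CoA acetyltransferase	0.13	0.07	E
I4WCN8	GpsA, glycerol-3-phosphate dehydrogenase	0.13	0.07	E
I4WDA0	acyl-CoA dehydrogenase	0.04	0.25	I
I4WE25	fatty acid binding protein	0.15	0.09	I
I4WE72	branched-chain alpha-keto acid dehydrogenase subunit E2	0.38	0.22	I
I4WEJ2	FabZ, 3-hydroxyacyl-[acyl-carrier-protein] dehydratase	—	0.29	I
I4WEK0	acetyl-coenzyme A carboxylase carboxyl transferase	—	0.04	I
I4WFP4	fatty acyl-CoA synthetase	0.16	0.05	E
I4WGM2	lipase	0.14	0.09	E
I4WIC3	acetyl-CoA acetyltransferase	0.23	0.62	I
I4WIC4	3-hydroxyacyl-CoA dehydrogenase	0.20	0.94	I
I4WJC3	polyhydroxyalkanoate depolymerase	0.07	—	I
I4WKE0	poly(R)-hydroxyalkanoic acid synthase, class III, PhaC subunit	0.14	0.05	I
I4WKE1	poly(R)-hydroxyalkanoic acid synthase subunit	0.05	—	E
I4WKH0	3-oxoacyl-[acyl-carrier-protein] synthase	0.12	0.21	I
I4WKH1	acyl carrier protein	0.11	—	I
I4WKH2	3-ketoacyl-[acyl-carrier-protein] reductase	0.20	0.04	E
I4WKH3	malonyl-CoA-acyl carrier protein transacylase	0.14	0.31	E
I4WKH4	3-oxoacyl-[acyl-carrier-protein] synthase	0.16	0.13	I
I4WKP8	acyl-CoA dehydrogenase	—	0.04	I
I4WM78	acyl-CoA dehydrogenase domain-containing protein	—	0.12	I
I4WM94	acyl-CoA dehydrogenase	—	0.06	E
I4WM95	acyl-CoA dehydrogenase	—	0.03	I
I4WM96	acetoacetate decarboxylase	0.20	0.13	E
I4WMY1	phasin	1.86	5.43	I
I4WP46	trans-2-enoyl-CoA reductase	0.11	0.25	I
I4WPL0	enoyl-CoA hydratase	0.19	0.20	I
I4WPU1	acyl-CoA dehydrogenase	—	0.05	E
I4WR42	acyl carrier protein	0.10	0.35	I
I4WR77	enoyl-CoA hydratase	0.08	—	I
I4WSC3	lipase	0.08	0.20	E
I4WSG8	acyl-CoA dehydrogenase	0.37	1.02	I
I4WU86	acyl-CoA thiolesterase	—	0.16	I
I4WUC2	lipase	—	0.07	E
I4WUD4	acetoacetyl-CoA reductase	0.17	—	E
I4WZ09	YdiF, acetate-CoA transferase	0.13	—	I
M4NHA9	acyl-CoA dehydrogenase	—	0.36	I
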