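genus	day5	day10	day20	day30	day60
Acidovorax	—	0.15	—	0.48	0.25
Acinetobacter	2.04	2.39	1.83	0.25	—
Afipia	—	—	—	—	0.24
Azospirillum	—	—	—	0.10	—
Bacteroides	—	—	—	—	0.02
Bordetella	—	0.19	—	—	—
Bradyrhizobium	—	0.05	0.16	0.29	0.44
Burkholderia	—	8.71	0.01	0.68	4.27
Comamonas	—	—	0.61	0.43	—
Cupriavidus	—	0.07	—	0.43	1.14
Elusimicrobium	—	—	—	0.03	—
Flavobacterium	—	—	—	—	0.02
Hyphomicrobium	—	—	—	—	0.06
Methylobacterium	—	—	0.65	0.09	0.19
Methylotenera	0.35	0.21	0.23	0.19	0.10
Mucilaginibacter	—	—	—	0.06	0.10
Myxococcus	—	—	0.02	—	—
Niastella	—	—	—	—	0.02
Oscillatoria	—	—	—	—	0.06
Patulibacter	—	1.49	1.08	0.08	—
Polynucleobacter	—	0.35	—	—	—
Pseudomonas	32.90	7.10	1.43	1.33	0.11
Ralstonia	—	0.08	0.16	3.68	4.17
Rhizobium	—	—	0.05	0.10	0.10
Rhodanobacter	—	—	—	0.03	0.35
Rhodopseudomonas	—	—	0.13	—	0.36
Rickettsia	—	—	—	0.11	0.33
Salinibacter	—	—	—	—	0.02
Serratia	1.21	—	—	—	—
Sphingomonas	—	—	—	—	0.05
Stenotrophomonas	—	—	—	—	0.06
Streptomyces	—	—	—	0.08	—
Variovorax	—	0.15	0.25	0.44	0.49
Unclassified	—	—	—	—	0.02
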