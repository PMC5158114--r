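# Ordered keyword rules mapping free-text annotations to suberin
# degradation/utilization pathway roles. First match (case-insensitive regex)
# wins; no match -> no role. Step "." means the role carries no step detail.
pattern	process	step
feruloyl[- ]esterase	feruloyl_esterase	.
lipid[- ]binding|YceI	suberin_adhesion	.
lipase|patatin	depolymerization	.
long[- ]chain[- ]fatty[- ]acid transport(er)?	long_chain_fatty_acid_transport	.
lipid transport	lipid_entry	.
CoA ligase|acyl[- ]?CoA synthetase	coa_activation	.
3-hydroxyacyl[- ]?CoA dehydrogenase|hydroxyacyl[- ]?CoA dehydrogenase	beta_oxidation	hydroxyacyl_coa_dehydrogenase
acyl[- ]?CoA dehydrogenase	beta_oxidation	acyl_coa_dehydrogenase
enoyl[- ]?CoA (hydratase|dehydratase)	beta_oxidation	enoyl_coa_hydratase
acetyl[- ]?CoA acetyltransferase|ketothiolase	beta_oxidation	acetyl_coa_acetyltransferase
fatty[- ]acid[- ]binding	regulation	.
acyl[- ]?CoA hydrolase	regulation	.
acyltransferase	acetyltransfer	.
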