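group	sgrna	mean_snvs_per_embryo	n_embryos_min
Cre	none	13	3
BE3	Tyr	225	3
ABE8e	Tyr	371	3
BE3	NT	270	3
ABE8e	NT	313	3
ABE8e	Dmd	279	4
ABE8e	Fah	343	3
ABE8e	PCSK9	387	3
ABE8e_Y149V	PCSK9	24	3
ABE8e_V82G	PCSK9	296	3
ABE8e_K20A_R21A	PCSK9	175	3
ABE8e_V106W	PCSK9	110	3
ABE9	PCSK9	37	3
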