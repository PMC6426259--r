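outcome	gene	stratum	beta_discovery	p_discovery	beta_replication	p_replication	beta_pooled
Firmicutes	CARD9	IBD	-0.38	2.3e-4	-0.08	0.50	-0.25
Bacteroides	NOD2	IBD	-0.62	1.9e-4	-0.05	0.58	-0.20
Roseburia	NOD2	IBD	-0.58	6.4e-5	-0.22	0.059	-0.36
F.prausnitzii	NOD2	IBD	-0.56	4.0e-4	-0.30	0.014	-0.40
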