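locus	kda	pep	cov	ral	sr	product
WD0611	28	8	36	4	0.2	UDP-N-acetylglucosamine pyrophosphorylase
WD0612	36	14	58	8	1.11	NAD-dependent epimerase/dehydratase
WD0613	90	22	31	10	0.49	Glycosyl transferase (group 1) moaA/nifB/pqqE family
WD0614	65	12	28	4.5	-0.47	Hypothetical with O-methyltransferase
WD0615	37	5	22	3.2	-0.37	Hypothetical with phytanoyl-CoA dioxygenase domain
WD0616	67	2	5	0.5	-2.68	ABC transporter, permease/ATP-binding protein
WD0617	39	12	42	3.8	-0.27	L-allo-threonine aldolase
WD0618	39	9	34	3.5	-0.02	L-allo-threonine aldolase
WD0619	44	0	0	0		GlpT/PgpT/UhpT transporter family protein
WD0620	48	12	33	3.5	-0.02	UDP-glucose 6-dehydrogenase
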