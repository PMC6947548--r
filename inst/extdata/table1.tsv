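# Catalogue of the 49 investigated homologous crystallized flavoprotein
# oxidoreductase structures: structural group, functional annotation,
# residue count, source organism, crystallized cofactors/inhibitors, and
# published backbone RMSD (Angstrom) against the three query structures
# (4bur AIF; 5kmr NDH-2; 4g73 NDI). "n.a." cells preserved as printed.
pdb_id	group	annotation	n_residues	organism	cofactors	inhibitors	rmsd_4bur	rmsd_5kmr	rmsd_4g73
4bur	AIF-like	AIF	511	H. sapiens	FAD/NADH	n.a.	0	3.12	2.22
5fs8	AIF-like	AIF	474	H. sapiens	FAD	n.a.	1.06	2.71	1.82
5vn0	AIF-like	NADH OX	449	L. brevis	FAD/NADH/O2	n.a.	2.28	2.03	2.18
1xhc	AIF-like	NADH OX/nitrile RED	555	P. furiosus	FAD	n.a.	1.799	2.443	2.458
2bc0	AIF-like	NADH OX	473	S. pyrogens	FAD	n.a.	1.53	1.859	1.658
2cdu	AIF-like	NAD(P)H OX	452	L. sanfrancensis	FAD/ADP	n.a.	2.226	2.2	2.095
1nhs	AIF-like	NADH PerOX	447	E. fecalis	FAD	n.a.	1.738	1.932	2.041
3lxd	AIF-like	Ferredoxin RED	409	E. coli	n.a.	n.a.	1.949	2.842	2.606
3fg2	AIF-like	Ferredoxin RED	404	R. palustris	FAD	n.a.	1.633	2.087	2.340
2gqw	AIF-like	Ferredoxin RED	401	Pseudomonas sp. KKS102	FAD	n.a.	1.986	2.362	2.365
2v3a	AIF-like	Rubredoxin RED	381	P. aeruginosa	FAD	n.a.	2.278	3.067	6.698
3klj	AIF-like	NADH:rubredoxin oxidoRED	378	C. acetobutylicum	FAD	n.a.	2.498	2.745	2.335
3ef6	AIF-like	Toluene 2,3-dioxygenase RED	400	P. putida	FAD	n.a.	1.914	1.979	2.146
1q1r	AIF-like	Putidaredoxin RED	421	P. putida	FAD	n.a.	1.581	2.85	3.069
3oc4	AIF-like	Pyridine nucleotide-disulfide oxidoRED	422	E. faecalis	FAD	n.a.	3.143	2.451	3.207
3iwa	AIF-like	Pyridine nucleotide-disulfide oxidoRED	397	D. vulgaris	n.a.	n.a.	2.243	3.06	2.664
3cgb	AIF-like	Pyridine nucleotide CoA-disulfide RED	444	B. anthracis	FAD/CoA	n.a.	2.17	2.37	2.341
4fx9	AIF-like	CoA disulfide RED	453	P. horikoshii	FAD/CoA	n.a.	2.148	2.223	2.488
3ics	AIF-like	CoA disulfide RED	555	B. anthracis	ADP/FAD/CoA	n.a.	1.845	1.958	1.98
3ntd	AIF-like	NADH-dependent persulfide RED	565	S. ioihica	FAD/CoA	n.a.	1.92	1.95	1.95
5kmr	NDH-2-like	Type II NADH DH	405	C. thermarum	FAD/NAD	n.a.	3.12	0	1.31
5n1t	NDH-2-like	FlavoCytC sulfide DH	393	T. paradoxus	CytC,COPC,FAD	n.a.	2.82	3.33	2.96
5na1	NDH-2-like	NADH:quinone oxidoRED	398	S. aureus	FAD	n.a.	2.63	0.82	1.39
5jwc	NDH-2-like	Type II NADH DH	495	P. falciparum	FAD	RYL-552	3.88	1.68	0.85
3hyw	NDH-2-like	Sulfide:quinone oxidoRED	429	A. aeolicus	FAD/DCQ/H2S	n.a.	3.52	2.75	2.86
4g73	NDI-like	Ndi1 NADH DH	502	S. cerevisiae	FAD/NAD/UQ5	n.a.	2.22	1.31	0
5yjw	NDI-like	Ndi1 NADH DH	454	S. cerevisiae	FAD	Stigmatellin	2.12	1.32	0.49
4m52	other DH	LD	465	M. tubercolosis	FAD	SL827	4.28	4.341	1.974
6aon	other DH	DLD	473	B. pertussis	n.a.	n.a.	4.84	2.03	3.76
4jq9	other DH	DLD	471	E. coli	FAD	n.a.	3.61	2.168	2.238
6awa	other DH	DLD	475	P. putida	FAD/AMP	n.a.	3.47	2.6	2.67
5j5z	other DH	DLD	477	H. sapiens	FAD	n.a.	3.23	2.77	3.13
1zmd	other DH	DLD	474	H. sapiens	FAD/NAD	n.a.	3.27	2.83	2.77
5u25	other DH	DLD	478	N. gonorrhoeae	FAD	n.a.	3.68	2.44	2.47
3urh	other DH	DLD	491	R. meliloti	FAD	n.a.	3.376	2.29	1.732
1lvl	other DH	LD	458	P. putida	FAD/NADH	n.a.	3.664	2.976	4.089
1ebd	other DH	DLD	455	G. stearothermophilus	FAD/Dihydrolipoamide acetyltransferase	n.a.	3.22	2.19	3.69
2yqu	other DH	LD	455	T. thermophilus	FAD	n.a.	3.884	3.548	2.97
3lad	other DH	Lipoamide DH	476	A. vinelandii	FAD	n.a.	4.442	2.221	2.995
2r9z	other DH	Glutathione amide RED	463	C. gracile	FAD	n.a.	2.813	2.396	2.046
6n7f	other DH	Glutathione RED	451	S. pyogenes	Riboflavin/FAD	n.a.	3.7	2.74	1.98
5vdn	other DH	Glutathione RED	449	Y. pestis	FAD	n.a.	3.73	2.41	2.66
4j56	other DH	Trx RED	504	P. falciparum	FAD/Trx	n.a.	3.45	3.33	2.01
1xdi	other DH	Flavoprotein disulfide RED	499	M. tuberculosis	FAD	n.a.	4.29	2.975	3.65
1mo9	other DH	NADPH:2-ketopropyl-CoM oxidoRED/carboxylase (2-KPCC)	523	X. autotrophicus	FAD	KPC	4.724	2.596	3.091
4k7z	other DH	Mercuric RED	467	P. aeruginosa	FAD/NADP	n.a.	3.807	3.341	3.498
4up3	outlier	Trx RED	312	E. histolytica	FAD/NADPH	n.a.	3.59	3.76	3.76
5u63	outlier	Trx RED	315	H. influenzae	FAD/NADP	n.a.	2.01	3.06	4.393
1ps9	outlier	2,4-dienoyl-CoA RED	671	E. coli	FMN/FAD/NADP	n.a.	2.02	3.93	2.16
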