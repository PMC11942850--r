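transcript	source	coefficient	avg_worker_tmm	avg_soldier_tmm	det
inositol 1,4,5-trisphosphate receptor mRNA	termite	-0.00015	97.58	18.41	no
resistance to inhibitors of cholinesterase protein 3 (RIC3) mRNA	termite	0.00121	803.25	2862.81	yes
T-box transcription factor TBX20 mRNA	termite	0.01148	24.28	127.13	yes
CAP-Gly domain-containing linker protein 2 (CLIP2) mRNA	termite	0.00022	187.64	1157.88	yes
periaxin mRNA	termite	-0.00178	172.28	3.17	yes
regulator of microtubule dynamics protein 1 (RMDN1) mRNA	termite	-0.00261	346.49	30.11	yes
CAP-Gly domain-containing linker protein 2 (CLIP2) mRNA	unclear	0.00105	656.38	3365.92	yes
choline transporter-like protein 2 (CTL2) mRNA	termite	-0.00071	960.42	141.31	yes
serine/threonine-protein kinase mRNA	unclear	4.56096	125.45	1099.15	no
Kazal-type serine protease inhibitor mRNA	unclear	1.95818	149.86	1717.32	yes
sorting nexin-29 (SNX29) mRNA	termite	-0.01008	173.60	12.24	yes
pancreatic triacylglycerol lipase (PTL) mRNA	termite	0.00021	287.63	2320.95	yes
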