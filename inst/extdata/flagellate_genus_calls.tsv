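gene	genus	order	best_pident	avg_worker_tmm	avg_soldier_tmm	adj_p
18S rRNA	Devescovina	Cristamonadida	92.55	1011.79	375.31	0.55
18S rRNA	Devescovina	Cristamonadida	95.75	105.92	64.66	0.78
18S rRNA	Devescovina	Cristamonadida	95.67	200.04	88.15	0.59
18S rRNA	Devescovina	Cristamonadida	91.80	197.95	175.36	0.95
18S rRNA	Oxymonas	Oxymonadida	94.78	547.68	908.43	0.71
18S rRNA	Oxymonas	Oxymonadida	92.41	90.92	178.40	0.59
18S rRNA	Oxymonas	Oxymonadida	96.83	147.28	271.46	0.70
18S rRNA	Oxymonas	Oxymonadida	97.46	869.33	1632.84	0.66
18S rRNA	Oxymonas	Oxymonadida	97.38	442.22	830.14	0.65
18S rRNA	Blattamonas	Oxymonadida	99.12	1468.43	2481.67	0.71
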