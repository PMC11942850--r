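gene	order	count
18S rRNA	Cristamonadida	10
18S rRNA	Oxymonadida	7
18S rRNA	Trichomonadida	2
18S rRNA	Tritrichomonadida	0
18S rRNA	unclassified	5
actin	Cristamonadida	63
actin	Oxymonadida	0
actin	Trichomonadida	4
actin	Tritrichomonadida	11
actin	unclassified	76
alpha tubulin	Cristamonadida	0
alpha tubulin	Oxymonadida	1
alpha tubulin	Trichomonadida	0
alpha tubulin	Tritrichomonadida	1
alpha tubulin	unclassified	48
beta tubulin	Cristamonadida	0
beta tubulin	Oxymonadida	0
beta tubulin	Trichomonadida	0
beta tubulin	Tritrichomonadida	0
beta tubulin	unclassified	56
EF1a	Cristamonadida	16
EF1a	Oxymonadida	0
EF1a	Trichomonadida	1
EF1a	Tritrichomonadida	0
EF1a	unclassified	10
GAPDH	Cristamonadida	5
GAPDH	Oxymonadida	0
GAPDH	Trichomonadida	0
GAPDH	Tritrichomonadida	0
GAPDH	unclassified	16
others	Cristamonadida	0
others	Oxymonadida	0
others	Trichomonadida	3
others	Tritrichomonadida	0
others	unclassified	98
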