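species	subfamily	genus	habitat	transcriptome_size	det_count	lt50	lt50_ci_half	utl
Cbom	Formicinae	Cataglyphis	desert	41912	253	44.83	0.18	43
Chol	Formicinae	Cataglyphis	desert	44525	54	46.00	0.16	45
Mbag	Formicinae	Melophorus	desert	38726	53	49.83	0.15	49
Orob	Myrmicinae	Ocymyrmex	desert	45701	698	46.80	0.16	43
Ffus	Formicinae	Formica	temperate	62416	4991	42.00	0.17	41
Msab	Myrmicinae	Myrmica	temperate	84784	10778	39.91	0.16	39
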