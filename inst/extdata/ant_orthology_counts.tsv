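species	n_genes	n_assigned	n_specific_og	n_genes_specific	n_og_containing
Cbom	46104	43429	712	2315	17645
Chol	46417	43520	859	2594	17924
Mbag	37949	34985	960	2904	16689
Orob	44826	41217	1637	5099	17837
Ffus	58025	53023	1748	6400	19473
Msab	58911	50192	3053	10333	20662
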