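gene_id	log2fc	pvalue	fdr
g01	2	0.0001	0.001
g02	-1	0.01	0.025
g03	1.2	0.002	0.01
g04	-0.8	0.005	0.0166667
g05	0.15	0.3	0.6
g06	-0.1	0.4	0.666667
g07	0.05	0.5	0.714286
g08	0.2	0.6	0.75
g09	-0.25	0.75	0.833333
g10	0.1	0.9	0.9
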