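PWY_A	worked impact example	g01	g02	g05	g06	g07
PWY_B	worked enrichment example	g01	g02	g03	g04	g08
PWY_C	set with members outside the universe	g09	g10	g11	g12
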