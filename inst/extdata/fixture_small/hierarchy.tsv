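pathway_id	pathway_name	subcategory	category
PWY_A	fixture pathway A	SC_metab	CAT_metab
PWY_B	fixture pathway B	SC_metab	CAT_metab
PWY_C	fixture pathway C	SC_info	CAT_info
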