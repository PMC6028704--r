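reaction_id	reversible	reactants	products
EX_glc	0		glc_D_e
GLCpts	0	glc_D_e;pep_c	g6p_c;pyr_c
PGI	1	g6p_c	f6p_c
PFK	0	f6p_c;atp_c	fdp_c;adp_c
FBA	1	fdp_c	dhap_c;g3p_c
TPI	1	dhap_c	g3p_c
GLYCL	0	g3p_c;adp_c	pep_c;atp_c
PYK	0	pep_c;adp_c	pyr_c;atp_c
EDD	0	g6p_c	g3p_c;pyr_c
MGS	0	dhap_c	pyr_c
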