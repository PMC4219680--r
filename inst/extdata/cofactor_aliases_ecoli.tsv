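# Example alias table for BiGG-style genome-scale ids (cytosolic
# compartment). Two tab-separated columns: alias<TAB>model-id. Edit to
# match the compartments your model actually uses.
H	M_h_c
AMP	M_amp_c
ADP	M_adp_c
ATP	M_atp_c
CoA	M_coa_c
NAD	M_nad_c
NADH	M_nadh_c
NADP	M_nadp_c
NADPH	M_nadph_c
phosphate	M_pi_c
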