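# source sugar plus the usual currency pool
glc_D_e
atp_c
adp_c
pep_c
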