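# planted products for background genes; one per line
# paired domain name after a tab (empty = no significant domain hit)
hypothetical protein
ABC transporter ATP-binding protein	ABC_tran
DNA polymerase III subunit alpha	DNA_pol3_alpha
MFS transporter	MFS_1
two-component system sensor kinase	HATPase_c
50S ribosomal protein L1	Ribosomal_L1
acyl-CoA dehydrogenase	Acyl-CoA_dh_1
LysR family transcriptional regulator	LysR_substrate
outer membrane porin	Porin_1
glutamine synthetase	Gln-synt_C
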