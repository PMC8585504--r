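# planted products for phage-annotated genes; one per line
# paired domain name after a tab (used for the synthetic domtblout)
phage tail protein	Phage_tail_2
terminase small subunit	Terminase_2
terminase large subunit	Terminase_GpA
phage portal protein	Phage_portal
phage major capsid protein	Phage_capsid
prophage integrase	Phage_integrase
phage baseplate assembly protein	Baseplate_J
bacteriophage holin	Phage_holin_1
phage tail tape measure protein	Tape_meas_TP901
phage antirepressor protein	ANT
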