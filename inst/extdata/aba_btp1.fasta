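>aba_BTP1 63-bp anti-BstA self-immunity element of prophage BTP1
GCCCGCCACACTTTAACAAGGAAAATCAAATGGTTAATCAGATAAGGTCCATATCACCCC
GCC
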