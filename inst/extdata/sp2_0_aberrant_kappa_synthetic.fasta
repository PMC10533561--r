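>sp2_0_aberrant_kappa_synthetic frameshifted non-productive kappa transcript (synthetic stand-in)






GCGGGCTGATGCTGCACCA
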