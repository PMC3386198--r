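>CoeEFV_PBS coelacanth endogenous foamy-like element, primer-binding site (consensus)
TGGCACCCAACGTGGGG
>HFV_PBS human foamy virus, primer-binding site
TGGCGCCCAACGTGGGG
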