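iucn,n_taxa
CR,7
EN,47
VU,16
NT,9
LC,125
DD,20
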