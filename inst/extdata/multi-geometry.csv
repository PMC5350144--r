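section,diameter_um,length_um,n_sections
dendrite,0.75,15,4
soma,5.8,5.6,1
AIS,1.5,2.5,1
axon,0.3,70,1
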