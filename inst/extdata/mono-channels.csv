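channel,kinetics,compartment,lo,hi,erev
Na,Na,soma,10.4,15.6,87.39
Nap,Nap,soma,1.6e-2,2.4e-2,87.39
Nar,Nar,soma,0.4,0.6,87.39
KV,KV,soma,2.4,3.6,-84.69
KA,KA,soma,3.2,4.8,-84.69
Kslow,Kslow,soma,0.28,0.42,-84.69
Kir,Kir,soma,0.72,1.1,-84.69
KCa,KCa,soma,3.2,4.8,-84.69
Ca-HVA,CaHVA,soma,0.37,0.55,ca
Lkg1,Lkg,soma,4.54e-2,6.82e-2,-58
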