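channel,kinetics,compartment,lo,hi,erev
Na,NaM,AIS,179.1,388.6,87.39
Na,NaM,axon,1.74,2.9,87.39
KV,KV,AIS,26.7,44.5,-84.69
KV,KV,axon,3.3,5.59,-84.69
KA,KA,soma,4,10,-84.69
Kslow,Kslow,soma,0.18,0.31,-84.69
Kir,Kir,soma,1.91,3.18,-84.69
KCa,KCa,dendrite,2.85,4.76,-84.69
Ca-HVA,CaHVA,dendrite,4.38,14.3,ca
Lkg,Lkg,dendrite,1.6908e-2,2.4798e-2,-16.5
Lkg,Lkg,soma,8.04e-2,0.13,-80.5
Lkg,Lkg,AIS,7.214e-2,0.25,-80.5
Lkg,Lkg,axon,6.4319e-3,1.071e-2,-80.5
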