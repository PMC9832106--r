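"label","MAP","CO","P_pv","PCG"
"baseline_low",76,4.65,10,4
"hypodynamic_low",60,3,10,4
"hyperdynamic_low",100,7,10,4
"baseline_high",76,4.65,18,14
"hypodynamic_high",60,3,18,14
"hyperdynamic_high",100,7,18,14
"baseline_mid",76,4.65,15,10
"hypodynamic_mid",60,3,15,10
"hyperdynamic_mid",100,7,15,10
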