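{"MAP":[50,130],"CO":[3,10],"P_pv":[3,20],"PCG":[1,14]}
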