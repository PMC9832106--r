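{"Ea_RA":{"family":"logistic","location":0.06,"scale":0.012,"lo":0.02,"hi":0.12},"Eb_RA":{"family":"uniform","location":0.03,"scale":0.07,"lo":0.03,"hi":0.1},"Ea_LV":{"family":"exponential","location":1,"scale":1.5,"lo":1,"hi":7},"Eb_LV":{"family":"normal","location":0.1,"scale":0.05,"lo":0.02,"hi":0.28},"R_pv":{"family":"cauchy","location":0.12,"scale":0.08,"lo":0.02,"hi":0.9},"R_ha":{"family":"logistic","location":20,"scale":4,"lo":8,"hi":45},"R_hv":{"family":"cauchy","location":0.19,"scale":0.12,"lo":0.04,"hi":1.1},"R_DO":{"family":"logistic","location":4.8,"scale":1.4,"lo":1.5,"hi":10},"R_OO":{"family":"cauchy","location":1.4,"scale":0.45,"lo":0.5,"hi":4},"hpx":{"family":"cauchy","location":0.35,"scale":0.15,"lo":0.05,"hi":0.95}}
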