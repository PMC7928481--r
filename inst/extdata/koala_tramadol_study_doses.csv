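subject,dose_mg,body_weight_kg,route
K1,18.2,9.1,sc
K2,13.70,6.85,sc
K3,31.60,7.90,sc
K4,30.60,7.65,sc
K5,27.80,6.95,sc
K6,30.0,7.50,sc
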