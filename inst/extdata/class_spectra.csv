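class,B2,B3,B4,B5,B6,B7,bt_k
vegetation,0.03,0.06,0.04,0.45,0.22,0.10,296
water,0.06,0.08,0.05,0.03,0.02,0.01,292
built_up,0.12,0.14,0.16,0.22,0.30,0.27,310
bare_soil,0.10,0.14,0.18,0.26,0.34,0.30,305
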