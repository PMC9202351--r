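# units: kcal/mol
table,method,mue,mape
ground,cas,3.64,78.75
ground,cas_disp,0.23,4.10
ground,ac0_cas,0.51,9.67
ground,lrac0_cas,0.20,4.25
ground,caspt2,0.33,5.37
ground,cas_revv10,0.42,9.03
ground,sapt,0.04,0.83
ground,lcbop_lrd,0.22,4.65
excited,cas,3.77,88.83
excited,cas_disp,0.24,5.93
excited,ac0_cas,0.61,13.27
excited,lrac0_cas,0.15,3.70
excited,caspt2,0.40,8.74
excited,cas_revv10,0.49,10.77
excited,sapt,0.23,4.85
excited,lcbop_lrd,0.28,5.12
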