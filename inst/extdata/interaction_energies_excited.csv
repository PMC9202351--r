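# units: kcal/mol
dimer,cas,cas_disp,ac0_cas,lrac0_cas,caspt2,cas_revv10,sapt,lcbop_lrd,reference
benzene-water,0.11,-2.43,-2.39,-2.82,-3.12,-2.93,-2.51,-2.88,-2.67
benzene-MeOH,0.96,-3.15,-2.62,-3.74,-3.42,-4.03,-3.25,-3.55,-3.49
benzene-MeNH2,1.51,-2.57,-2.40,-3.00,-3.24,-3.46,-2.62,-2.74,-2.80
pyridine-water,-4.20,-7.41,-6.61,-7.34,-7.90,-6.37,-6.91,-7.96,-7.15
pyridine-MeOH,-4.01,-7.97,-6.72,-7.91,-7.21,-6.98,-7.44,-8.37,-7.70
pyridine-MeNH2,0.61,-3.73,-3.43,-4.11,-3.96,-4.24,-3.82,-4.06,-4.19
peptide-water,-2.23,-4.70,-4.23,-4.52,-4.92,-4.29,-4.36,-4.81,-4.63
peptide-MeNH2,-2.08,-6.76,-6.18,-6.82,-7.28,-6.23,-6.40,-6.97,-6.82
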