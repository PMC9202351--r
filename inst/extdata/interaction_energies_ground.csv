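# units: kcal/mol
dimer,cas,cas_disp,ac0_cas,lrac0_cas,caspt2,cas_revv10,sapt,lcbop_lrd,reference
benzene-water,-0.53,-3.20,-2.99,-3.45,-3.13,-3.58,-3.27,-3.33,-3.29
benzene-MeOH,0.30,-3.98,-3.74,-4.42,-4.14,-4.71,-4.08,-3.91,-4.17
benzene-MeNH2,1.14,-3.10,-2.91,-3.46,-3.29,-3.85,-3.18,-2.92,-3.20
pyridine-water,-4.20,-7.43,-6.21,-7.27,-5.44,-6.37,-6.95,-7.17,-6.97
pyridine-MeOH,-4.00,-8.00,-6.73,-7.85,-7.22,-6.98,-7.49,-7.50,-7.51
pyridine-MeNH2,0.59,-3.87,-3.56,-4.17,-4.02,-4.28,-3.96,-3.55,-3.97
peptide-water,-3.03,-5.49,-4.79,-5.18,-4.94,-5.11,-5.15,-5.09,-5.20
peptide-MeNH2,-3.01,-7.65,-6.85,-7.50,-7.37,-7.20,-7.45,-7.16,-7.56
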