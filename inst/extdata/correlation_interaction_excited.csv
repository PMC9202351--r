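# units: kcal/mol
dimer,e_disp_total,ac0,lrac0,revv10,lrd
benzene-water,-2.55,-2.50,-2.93,-3.04,-1.07
benzene-MeOH,-4.11,-3.58,-4.70,-4.99,-1.84
benzene-MeNH2,-4.08,-3.91,-4.51,-4.97,-1.95
pyridine-water,-3.21,-2.41,-3.14,-2.16,-0.56
pyridine-MeOH,-3.96,-2.71,-3.90,-2.97,-0.92
pyridine-MeNH2,-4.34,-4.04,-4.72,-4.85,-1.71
peptide-water,-2.47,-2.00,-2.29,-2.07,-0.53
peptide-MeNH2,-4.69,-4.10,-4.74,-4.15,-1.30
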