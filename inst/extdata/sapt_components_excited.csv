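# units: kcal/mol
dimer,e_elst1,e_exch1,e_ind2,e_exch_ind2,e_disp2,e_exch_disp2,e_int_sapt,eps_disp_1to0
benzene-water,-1.85,2.82,-1.23,0.65,-2.88,0.33,-2.16,-0.04
benzene-MeOH,-2.10,4.07,-1.57,0.96,-4.63,0.52,-2.76,-0.06
benzene-MeNH2,-1.68,3.73,-1.12,0.88,-4.62,0.54,-2.28,-0.02
pyridine-water,-11.23,10.66,-5.17,2.96,-4.05,0.84,-5.99,-0.07
pyridine-MeOH,-11.79,11.79,-5.92,3.53,-4.95,0.99,-6.37,-0.08
pyridine-MeNH2,-3.89,5.46,-1.79,1.30,-5.01,0.66,-3.27,-0.08
peptide-water,-5.99,5.33,-1.95,1.01,-2.93,0.46,-4.09,0.00
peptide-MeNH2,-9.84,10.91,-5.04,3.35,-5.78,1.10,-5.30,0.00
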