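# Reported equilibrium dissociation constants used for report
# annotation.  These are literature reference values for the
# B1.23.2/HLA system, not quantities computed by this package.
label,kd_molar,kd_display,source
B*44:05 wt,2.0e-8,0.02 uM,"SPR single-cycle kinetics, wild-type HLA-B*44:05 / antibody"
peptide S8T,8e-9,~8 nM,"peptide position-8 substitution series, strongest binder"
peptide S8E,9e-8,~90 nM,"peptide position-8 substitution series, weakest binder"
A*02:01 T142I/H145R/H151R,9.0e-6,9.0 uM,"alpha2-1 transplant mutant series (triple)"
A*02:01 T142I/K144Q/H145R,4.0e-8,0.04 uM,"alpha2-1 transplant mutant series (triple)"
quadruple mutant,7.0e-9,0.007 uM,"alpha2-1 transplant mutant series (T142I/K144Q/H145R/H151R)"
KIR/HLA min,9.5e-6,9.5 uM,"reported KIR/HLA affinity range, lower bound"
KIR/HLA max,1.7e-5,17 uM,"reported KIR/HLA affinity range, upper bound"
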