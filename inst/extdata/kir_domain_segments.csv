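# Approximate Ig-domain boundaries (author numbering) for the receptor
# chains of the two KIR/HLA comparison structures, used to attribute
# clashes to D0/D1/D2.  These are standard two/three-domain KIR
# boundaries, not values read from the depositions; override via hints
# when exact ranges are required.
accession,segment,start,end
1EFX,D1,6,101
1EFX,D2,102,200
3VH8,D0,1,96
3VH8,D1,97,197
3VH8,D2,198,298
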