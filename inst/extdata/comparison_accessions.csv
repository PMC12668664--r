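# Coordinate accessions used by the regression and comparison analyses
# (user-supplied files; the package never downloads).  The TCR complex
# list supports optional user-driven footprint runs and is not part of
# any packaged analysis.
accession,kind,description
9D73,cryo-EM,antibody (full mAb sample) + HLA-B*44:05 complex
9D74,cryo-EM,antibody Fab + HLA-B*44:05 complex
8TQ6,X-ray,antibody Fab + HLA-B*44:05 complex
9OA9,cryo-EM,antibody Fc region
1EFX,X-ray,KIR2DL2 + HLA-C*03:04 complex
3VH8,X-ray,KIR3DL1 + HLA-B*57:01 complex
1OGA,X-ray,TCR complex (footprint comparison; optional)
1AO7,X-ray,TCR complex (footprint comparison; optional)
1BD2,X-ray,TCR complex (footprint comparison; optional)
1LP9,X-ray,TCR complex (footprint comparison; optional)
2BNQ,X-ray,TCR complex (footprint comparison; optional)
3HG1,X-ray,TCR complex (footprint comparison; optional)
3GSN,X-ray,TCR complex (footprint comparison; optional)
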