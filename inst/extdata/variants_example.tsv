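label	zygosity	evidence	icc_pm_localized
V67D	homozygous	none	0
A170E	compound_het	clinvar_benign	1
R555W	homozygous	none	0
L1341P	homozygous	none	0
I1607T	compound_het	two_other_pathogenic	1
K1526T	compound_het	cis_with_pathogenic	1
R2042C	homozygous	none	0
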