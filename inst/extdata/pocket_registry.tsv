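pocket_name	lining_residues	atp_site
aD-L13	118,183,221	FALSE
L4-L7	81,82,83,84,86	FALSE
P-aC	67,74,171	FALSE
aG-L14	222,237,273	FALSE
aE-L16	140,317,320	FALSE
aE-L16b	125,132,311	FALSE
P-L12	193,197,199	FALSE
L12	177,185,194	FALSE
aE-b7	116,126,162	FALSE
aC-aL16	73,76,344	FALSE
b5-aL16	88,92,346	FALSE
P-L16	145,146,70,325,326	FALSE
MKI	242,249,259	FALSE
ATP	34,35,169,109	TRUE
aE-aF	142,202,299	FALSE
aH-MKI	241,269,289	FALSE
aF-aG	207,214,235	FALSE
b2-L4	16,17,57	FALSE
aE-L4	82,134,137	FALSE
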