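comparison	level	total	prok_only
simMG:MG	KO	76.21	81.05
simMG:MT	KO	49.05	55.68
MG:MT	KO	59.46	65.50
simMG:MG:MT	KO	44.50	50.94
simMG:MG	EC	76.14	78.03
simMG:MT	EC	61.94	62.54
MG:MT	EC	68.13	67.73
simMG:MG:MT	EC	54.57	55.42
simMG:MG	pathway	75.29	84.27
simMG:MT	pathway	63.15	69.51
MG:MT	pathway	73.08	74.16
simMG:MG:MT	pathway	55.12	63.46
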