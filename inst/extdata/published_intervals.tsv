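method	chrom	start	end
ED	Chr02	0	5620000
ED	Chr03	59020000	62280000
ED	Chr07	48360000	48380000
SNP-index	Chr02	0	6370000
SNP-index	Chr05	26160000	26380000
SNP-index	Chr05	26400000	26440000
SNP-index	Chr05	37170000	38150000
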