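trait	n_as_snps	n_loci
Blood protein levels	1	1
Cholesterol, total	1	1
Fibrinogen	1	1
Total	3	2
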