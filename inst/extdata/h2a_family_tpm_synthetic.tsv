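gene_id	subtype	tpm
H2afb1	H2A.B	0.65
H2afb2	H2A.B	0.65
H2afb3	H2A.B	0.65
H2afz	H2A.Z	16.85
H2afv	H2A.Z	16.85
Hist1h2aa	H2A	1.06
Hist1h2ab	H2A	1.06
Hist1h2ac	H2A	1.06
Hist1h2ad	H2A	1.06
Hist1h2ae	H2A	1.06
Hist1h2af	H2A	1.06
Hist1h2ag	H2A	1.06
Hist1h2ah	H2A	1.06
Hist1h2ai	H2A	1.06
Hist1h2ak	H2A	1.06
Hist1h2an	H2A	1.06
Hist1h2ao	H2A	1.06
Hist2h2aa1	H2A	1.06
Hist2h2aa2	H2A	1.06
Hist2h2ab	H2A	1.06
Hist2h2ac	H2A	1.06
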