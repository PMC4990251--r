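name	peptide_family	transcript_length_bp	evalue	score	genbank_accession
BnVP-like	Arginine-vasotocine	599	4.00E-09	61.2	KX095876
BnPEP-like	Pedal peptide/orcokinin neuropeptide	792	1.00E-05	55.1	KX095877
BnFDSIG-like	Pedal peptide/orcokinin neuropeptide	697	1.00E-10	72	KX095878
BnNPF-like	Neuropeptide Y	476	8.00E-10	61.6	KX095879
BnGHB	Glycoprotein hormone-beta5-I	949	6.00E-08	57.4	KX095880
BnILP-A	Insulin-like peptide	1220	3.00E-27	112	KX095882
BnINS_B	Insulin-like peptide	371	4.00E-25	44.3	KX095885
BnINS_C	Insulin-like peptide	675	3.00E-04	59.7	KX095886
BnILP-D	Insulin-like peptide	1029	5.00E-08	59.3	KX095881
BnILP-E	Insulin-like peptide	696	1.00E-11	69.3	KX095883
BnILP-F	Insulin-like peptide	547	5.00E-17	83.6	KX095884
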