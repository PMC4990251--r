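precursor	peptide_name	partial	printed_sequence
BnFDSIG-like	P1	FALSE	SFDSIGNGPIGLKR
BnFDSIG-like	P2	FALSE	SFDGIGNGPIGLKR
BnFDSIG-like	P3	FALSE	SRDSIGFGPIGLKR
BnFDSIG-like	P4	FALSE	SFGGIGGRPASYKR
BnPep-like	P1	FALSE	YLERIGSGNALISKR
BnPep-like	P2	FALSE	YLERIGSGNSVIKK
BnPep-like	P3	FALSE	QHLKGSGENSLPKKR
BnPep-like	P4	FALSE	YLERIGSGNELVGKR
BnPep-like	P5	TRUE	YLERIGSGND
BnVP-like	Vasopressin-like	FALSE	CYIRTCDLGILGKR
BnVP-like	Neurophysin	FALSE	TVEGKPALCRACGPGLAGQCYGNSYCCGYFGCYNVRKTDECQISSPTQSRLCKKGFSPCFTIPGGSCSANGFCCNSDTCRPSLTCVRLTNLYGEPEKHHRV
BnGHB5	Mature	FALSE	TPVPFPASGCNLITVRLNVTNGANSHCWGLIDFSGCGGYCESYDIILPEPPYRDRHHQVCGFADYEHVETILANCHQGYSPEVFKFPKVTSCSCRECDPMREVCM
BnNPFL	Mature	FALSE	GPPEPQSKFKSPEELKQYLKSLEEY(SOH)LAY(SOH)NDPVRFGKR
BnILP-A	ChainB	FALSE	DFEHMCVHEDFSRSGAYSSCGSRLTSLVISKCDGNPYLASRGKR
BnILP-A	ChainC	FALSE	DLEKISLTTESANSYLRPKR
BnILP-A	ChainA	FALSE	NYEYVEDGMGVGIICECCVNTCTIRELDQYCESKR
BnILP-B	ChainB	FALSE	GTSAEEYKVCTIKDSPNPRGMCGSQVFKQIYVICNGNIYSSGFLTSPDRR
BnILP-B	ChainC	FALSE	AIRPHVSDISSNRNTANSFLSQSKR
BnILP-B	ChainA	FALSE	QFEFLEDERDARMMGIHCECCIHTCTLEEKQEYCGSKR
BnILP-C	ChainB	FALSE	TFSAAELTHTCTYERLTSGYHGRMSRCGGELTDYVLSKCYGYQPYRRRR
BnILP-C	ChainC	FALSE	AVSTLLNNTPDKQVIKQQETTEANSVFKSHSKANEFLFRQKR
BnILP-C	ChainA	FALSE	QHGGFIPSNSQGIVCECCVYGCNDNEIMQYCEEFKR
BnILP-D	ChainB	FALSE	LERICHMDDQSNKDPGLCRRRLQLYLSRICNGDITPIK
BnILP-D	ChainC	FALSE	HNHITEQLSESEQNPTTANPISGISSSRETANAFLNHSKR
BnILP-D	ChainA	FALSE	QQAESDDVNTFSGIICECCFHPCSEYELSEYCGSKRRRKR
BnILP-E	ChainB	FALSE	DFEHTCQTDVQSPYTFCGQILTNMVFDKCGDER
BnILP-E	ChainC	FALSE	LSQLAVLDVGVTASITHDIFISAKK
BnILP-E	ChainA	FALSE	ANSLLMFSAGLNAESGIYCECCVNRCTVTELEQYCNPLAAIQPRLRR
BnILP-F	ChainB	TRUE	PYINKR
BnILP-F	ChainC	FALSE	AFDDDSKNQPRVSQNIFVSKNHSNEFLNPKR
BnILP-F	ChainA	FALSE	NGHERSQYGVVCECCINPCTLREMQAYCAKKR
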