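source	promoter_id	chrom	start	end	declared_span
PrESSTo/FANTOM	P1@MGMT	chr10	129466944	129467344	401
PrESSTo/FANTOM	P2@MGMT	chr10	129466905	129467305	401
EPD	MGMT_1	chr10	129466745	129467344	600
NCBI/Nucleotide	X61657.1	chr10	129466183	129467339	1157
Ensembl 84	ENSR00001428452	chr10	129466558	129468201	1644
this study	MGMT-P1	chr10	129466183	129468201	2019
TRED	TRED-5071	chr10	129535540	129536539	1000
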