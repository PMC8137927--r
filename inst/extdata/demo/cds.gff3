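##gff-version 3
SYN0001	ribo40s	CDS	109	330	.	+	0	ID=SYN0001_CDS;Parent=SYN0001
SYN0002	ribo40s	CDS	97	336	.	+	0	ID=SYN0002_CDS;Parent=SYN0002
SYN0003	ribo40s	CDS	61	339	.	+	0	ID=SYN0003_CDS;Parent=SYN0003
SYN0004	ribo40s	CDS	85	279	.	+	0	ID=SYN0004_CDS;Parent=SYN0004
SYN0005	ribo40s	CDS	70	285	.	+	0	ID=SYN0005_CDS;Parent=SYN0005
SYN0006	ribo40s	CDS	96	419	.	+	0	ID=SYN0006_CDS;Parent=SYN0006
SYN0007	ribo40s	CDS	78	251	.	+	0	ID=SYN0007_CDS;Parent=SYN0007
SYN0008	ribo40s	CDS	118	375	.	+	0	ID=SYN0008_CDS;Parent=SYN0008
SYN0009	ribo40s	CDS	109	462	.	+	0	ID=SYN0009_CDS;Parent=SYN0009
SYN0010	ribo40s	CDS	107	514	.	+	0	ID=SYN0010_CDS;Parent=SYN0010
SYN0011	ribo40s	CDS	84	287	.	+	0	ID=SYN0011_CDS;Parent=SYN0011
SYN0012	ribo40s	CDS	67	492	.	+	0	ID=SYN0012_CDS;Parent=SYN0012
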