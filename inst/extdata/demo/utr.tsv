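gene_id	utr5_len	utr3_len	utr5_intron
SYN0001	108	116	FALSE
SYN0002	96	99	FALSE
SYN0003	60	105	FALSE
SYN0004	84	82	FALSE
SYN0005	69	120	FALSE
SYN0006	95	106	FALSE
SYN0007	77	115	FALSE
SYN0008	117	84	FALSE
SYN0009	108	113	FALSE
SYN0010	106	82	FALSE
SYN0011	83	137	FALSE
SYN0012	66	121	FALSE
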