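sample_id	status	age	sex	PC1	PC2
S1	1	58	female	0.01	-0.02
S2	0	70	male	-0.03	0.04
S3	1	.	female	0.02	0.01
S4	0	64	male	0.00	-0.01
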