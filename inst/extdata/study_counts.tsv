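population	stage	IS	CE	LAS	SVS	controls
ASGC	I	1162	240	421	310	1244
WTCCC2-Germany	I	1174	330	346	106	797
WTCCC2-UK	I	2374	474	498	460	5175
Milano	I	366	64	73	25	407
DNA-lacunar/GENESIS	I	1287	80	64	1012	970
LSS	I	455	157	70	55	455
ISGS/SWISS	I	1014	235	217	187	1370
BRAINS	I	361	29	120	97	444
MGH-GASROS	I	294	106	68	23	376
VISP	I	1723	.	.	.	1047
SiGN	II	7743	2001	1130	1408	17970
deCODE	III	.	1100	.	520	20473
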