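cell	DA01	DB01	DD01	VA01	MDL08	MVR01	AIYL
DA01	0	0	2	0	3	0	1
DB01	0	0	1	0	5	0	0
DD01	1	2	0	0	4	0	0
VA01	0	0	0	0	0	2	0
AVBL	0	3	0	0	0	0	0
MDL08	1	0	0	0	0	0	0
AIYL	2	0	0	0	0	0	0
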