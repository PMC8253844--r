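cell	DA01	DA02	DB01	MDL08	MDL09	MVR01
DA01	0	2	1	0	0	0
DA02	2	0	0	0	0	0
DB01	1	0	0	2	0	0
MDL08	0	0	2	0	3	0
MDL09	0	0	0	3	0	0
MVR01	0	0	0	0	0	0
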