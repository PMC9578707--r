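gene	brain	heart	liver	lung	kidney	muscle	spleen	skin
SYNA1	9	1	1	2	1	1	2	1
SYNA2	8	2	1	2	1	1	2	2
SYNA3	7	1	2	3	1	2	1	1
SYNB1	1	8	7	1	2	9	1	1
SYNB2	2	7	8	1	1	8	2	1
SYNC1	3	3	3	3	3	3	3	9
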