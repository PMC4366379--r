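start	end	kind	ref	alt	JI1794	721	L100	VIR320
1	11	terminal_absence	MINEDPSSLTD	.	0	1	1	1
46	46	replacement	D	H	1	1	1	1
47	47	replacement	K	T	0	0	1	1
48	48	replacement	I	L	0	1	0	0
109	109	replacement	R	S	0	1	1	1
112	112	replacement	I	R	1	0	0	0
116	116	replacement	R	T	0	1	0	0
130	135	deletion	ISDTND	.	0	1	1	0
141	143	insertion	.	DTN	1	0	0	0
175	180	insertion	.	ISDTND	0	1	1	1
196	203	deletion	TNIKDICE	.	0	0	1	1
210	210	replacement	P	R	0	1	1	1
214	214	deletion	E	.	0	0	1	1
224	225	replacement	SD	IH	0	0	1	1
240	240	replacement	E	R	0	0	1	1
249	249	replacement	Q	P	1	0	1	1
309	339	deletion	.	.	0	1	1	1
340	342	deletion	EEE	.	0	0	1	1
345	345	replacement	Q	P	0	1	0	0
375	376	replacement	HP	NR	0	1	1	1
379	379	replacement	E	Q	0	0	1	1
383	383	replacement	N	K	0	0	1	1
384	384	replacement	Q	K	0	1	1	1
399	399	insertion	.	E	0	1	1	0
399	399	insertion	.	Q	0	0	0	1
400	401	insertion	.	EE	0	1	0	0
407	407	replacement	Q	P	0	1	0	0
559	559	replacement	E	Q	0	0	1	1
603	610	terminal_addition	.	SNWTENEN	1	0	0	0
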