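start	end	kind	ref	alt	JI1794	721	L100	VIR320
70	70	replacement	T	A	0	0	1	0
130	130	replacement	M	L	0	0	0	1
135	135	replacement	S	N	1	0	1	1
159	159	replacement	M	T	1	0	0	0
179	179	replacement	A	T	1	0	1	1
211	211	replacement	M	I	1	0	0	0
211	211	replacement	M	T	0	0	1	1
252	252	replacement	H	Y	0	0	1	1
254	254	replacement	V	I	0	0	1	1
279	279	replacement	M	I	0	0	1	1
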