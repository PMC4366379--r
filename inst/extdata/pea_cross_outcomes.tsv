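cytoplasm_donor	nuclear_donor	outcome
VIR320	L100	compatible
L100	VIR320	compatible
VIR320	WL1238	incompatible
VIR320	JI1794	incompatible
VIR320	721	incompatible
L100	WL1238	incompatible
L100	721	incompatible
WL1238	VIR320	compatible
JI1794	VIR320	compatible
WL1238	JI1794	compatible
JI1794	WL1238	compatible
WL1238	721	incompatible
WL1238	L100	incompatible
721	WL1238	partial
721	L100	compatible
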