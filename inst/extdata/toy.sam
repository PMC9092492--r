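@HD	VN:1.6	SO:coordinate
@SQ	SN:c1	LN:300
r1	0	c1	100	60	1M	*	0	0	C	I
r2	0	c1	100	60	1M	*	0	0	C	I
r3	0	c1	100	60	1M	*	0	0	C	I
r4	0	c1	100	60	1M	*	0	0	T	I
r5	0	c1	100	60	1M	*	0	0	C	I
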