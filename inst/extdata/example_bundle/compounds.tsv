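id	name	mass
M1	M1	180.16
M5	M5	100.1
D1	D1	120.1
M2	M2	510.3
M3	M3	520.4
M4	M4	480.2
D2	D2	530.1
D3	D3	540.7
P	P	410.5
ATP	ATP	507.2
ADP	ADP	427.2
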