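reaction_id	substrate_id	product_id	category
R1	M1	M2	main
R2	M2	M3	main
R3	M3	P	main
R4	M5	M4	main
R5	D1	D2	main
R6	D2	D3	main
R7	D3	M3	main
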