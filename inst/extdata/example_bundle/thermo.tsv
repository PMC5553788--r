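reaction_id	drG_m_kJ_mol
R1	-20
R2	-5
R3	-25
R4	
R5	-18
R6	-18
R7	-18
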