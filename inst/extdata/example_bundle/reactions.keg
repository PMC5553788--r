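ENTRY       R1                   Reaction
EQUATION    M1 + ATP <=> M2 + ADP
///
ENTRY       R2                   Reaction
EQUATION    M2 <=> M3
///
ENTRY       R3                   Reaction
EQUATION    M3 + M4 <=> P
///
ENTRY       R4                   Reaction
EQUATION    M5 <=> M4
///
ENTRY       R5                   Reaction
EQUATION    D1 <=> D2
///
ENTRY       R6                   Reaction
EQUATION    D2 <=> D3
///
ENTRY       R7                   Reaction
EQUATION    D3 <=> M3
///
ENTRY       RX901                Reaction
EQUATION    C90001 <=> C90002
COMMENT     generic reaction
///
ENTRY       RX902                Reaction
EQUATION    C90003 <=> C90004
COMMENT     incomplete reaction
///
ENTRY       RX903                Reaction
EQUATION    n C90005 <=> n C90006
///
ENTRY       RX904                Reaction
EQUATION    G90001 <=> C90007
///
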