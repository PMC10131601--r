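diag_code,p_emergent,p_nonemergent,p_other
R07.9,0.55,0.35,0.10
R10.9,0.40,0.50,0.10
J06.9,0.10,0.85,0.05
S93.4,0.25,0.70,0.05
R51.9,0.20,0.70,0.10
I21.9,0.95,0.00,0.05
J45.9,0.60,0.30,0.10
N39.0,0.30,0.60,0.10
R42.0,0.45,0.45,0.10
S01.0,0.35,0.60,0.05
K52.9,0.25,0.65,0.10
R50.9,0.30,0.60,0.10
M54.5,0.10,0.80,0.10
J18.9,0.80,0.10,0.10
R06.0,0.70,0.20,0.10
T14.9,0.30,0.60,0.10
H66.9,0.05,0.90,0.05
L03.9,0.40,0.50,0.10
G43.9,0.35,0.55,0.10
R11.2,0.35,0.55,0.10
I63.9,0.97,0.00,0.03
S52.5,0.60,0.35,0.05
F41.9,0.25,0.55,0.20
E86.0,0.50,0.40,0.10
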