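group	models	set_size
MTORG	105	42
AutRG	101	95
TolRG	110	22
AISRG	101	101
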