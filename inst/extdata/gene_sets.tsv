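symbol	tag
PACRG	cilia
TCTN2	cilia
DNAH10	cilia
TTC40	cilia
NUMB	pathway:Notch
RNF115	e3_ligase
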