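symbol
ZIC3
CFC1
NKX2.5
GDF1
NODAL
LEFTY1
LEFTY2
ACVR2B
DNAH5
DNAH11
DNAI1
FOXH1
CRELD1
GALNT11
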