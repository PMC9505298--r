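hexamer	percent
AAUAAA	51.64
AUUAAA	12.15
UAUAAA	4.38
AGUAAA	4.17
AAGAAA	2.63
AAUAUA	2.42
AAUACA	2.32
CAUAAA	2.00
GAUAAA	2.01
AAUGAA	1.64
UUUAAA	1.25
ACUAAA	1.19
AAUAGA	1.05
AAAAAG	1.03
Other	10.13
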