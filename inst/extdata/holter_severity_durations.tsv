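level	name	duration
0	noise-free	9 h 42 m 35 s
1	low	5 d 18 h 54 m 2 s
2	moderate	2 h 52 m 35 s
3	hard	20 m 52 s
4	other	16 h 41 m 52 s
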