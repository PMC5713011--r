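level	name	duration
0	noise-free	3 h 27 m 56 s
1	low	3 h 1 m 15 s
2	moderate	4 h 4 m 50 s
3	hard	1 h 29 m 18 s
4	other	53 m 27 s
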