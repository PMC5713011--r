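level;name;lead1_s;lead2_s
0;noise-free;33602,99;36306,41
1;low;500037,07;500046,92
2;moderate;10355,21;10355,13
3;hard;1252,02;1252,02
4;other;61468,7;58755,52
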