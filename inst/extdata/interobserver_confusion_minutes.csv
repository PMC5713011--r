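"","Free","Low","Moderate","Hard","Others"
"Free",3.67,1.86,0.00,0.00,0.00
"Low",0.30,20.46,0.29,0.00,0.00
"Moderate",0.05,6.92,6.88,0.01,0.00
"Hard",0.00,0.03,0.06,2.14,0.01
"Others",0.00,0.00,0.00,0.00,5.08
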