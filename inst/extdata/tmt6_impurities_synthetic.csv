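channel,minus2,minus1,plus1,plus2
126,0,0,6.1,0.2
127,0,0.5,5.4,0.1
128,0.1,1.2,4.7,0.2
129,0.1,1.9,4.2,0.1
130,0.2,2.6,3.6,0
131,0.2,3.1,2.9,0
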