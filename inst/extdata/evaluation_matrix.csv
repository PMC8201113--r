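functional,d1,d2,d3,d4,d5
1,Q,A,A,A,O
2,R,I,I,I,M
3,R,I,I,I,M
4,R,I,I,I,M
5,R,R,R,R,Q
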