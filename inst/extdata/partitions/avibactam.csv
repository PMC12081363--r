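a,b,count
1,3,3
1,4,4
2,2,1
2,3,3
3,3,4
2,4,3
3,4,1
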