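a,b,count
1,3,5
1,4,3
2,2,4
2,3,4
3,3,6
2,4,2
3,4,3
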