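a,b,count
1,2,1
1,3,6
2,2,6
2,3,10
3,3,5
2,4,2
3,4,1
1,4,1
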