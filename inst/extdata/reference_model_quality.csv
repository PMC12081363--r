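degree,descriptor,property,r2_printed,r_printed
1,B1,En,0.824,0.9077
1,B1,MR,0.8964,0.9468
1,B1,MV,0.8519,0.9230
1,B1,FP,0.864,0.9295
1,B1,MW,0.9125,0.9552
1,B2,En,0.8081,0.8989
1,B2,MR,0.8513,0.9227
1,B2,MV,0.862,0.9284
1,B2,FP,0.8393,0.9161
1,B2,MW,0.8099,0.8999
1,HB1,En,0.8203,0.9057
1,HB1,MR,0.8571,0.9258
1,HB1,MV,0.8647,0.9299
1,HB1,FP,0.9204,0.9594
1,HB1,MW,0.8144,0.9024
1,HB2,En,0.8143,0.9024
1,HB2,MR,0.8378,0.9153
1,HB2,MV,0.8174,0.9041
1,HB2,FP,0.838,0.9154
1,HB2,MW,,
1,Hb,En,0.8719,0.9338
1,Hb,MR,0.9204,0.9594
1,Hb,MV,0.9012,0.9493
1,Hb,FP,0.8822,0.9393
1,Hb,MW,0.9627,0.9812
2,B1,En,0.8861,0.9413
2,B1,MR,0.9105,0.9542
2,B1,MV,0.9196,0.9590
2,B1,FP,0.8773,0.9366
2,B1,MW,0.9287,0.9637
2,B2,En,0.948,0.9737
2,B2,MR,0.8596,0.9271
2,B2,MV,0.902,0.9497
2,B2,FP,0.8735,0.9346
2,B2,MW,0.8304,0.9113
2,HB1,En,0.9421,0.9706
2,HB1,MR,0.8738,0.9348
2,HB1,MV,0.9238,0.9611
2,HB1,FP,0.9245,0.9615
2,HB1,MW,0.8395,0.9162
2,HB2,En,0.866,0.9306
2,HB2,MR,0.8575,0.9260
2,HB2,MV,0.8175,0.9042
2,HB2,FP,0.8779,0.9370
2,HB2,MW,,
2,Hb,En,0.8869,0.9418
2,Hb,MR,0.9205,0.9594
2,Hb,MV,0.9228,0.9606
2,Hb,FP,0.8825,0.9394
2,Hb,MW,0.9647,0.9822
3,B1,En,0.8907,0.9438
3,B1,MR,0.9263,0.9624
3,B1,MV,0.9329,0.9659
3,B1,FP,0.8775,0.9367
3,B1,MW,0.934,0.9664
3,B2,En,0.9483,0.9738
3,B2,MR,0.8702,0.9328
3,B2,MV,0.9159,0.9570
3,B2,FP,0.8944,0.9457
3,B2,MW,0.8521,0.9231
3,HB1,En,0.9431,0.9711
3,HB1,MR,0.8863,0.9414
3,HB1,MV,0.9338,0.9663
3,HB1,FP,0.9269,0.9628
3,HB1,MW,0.8575,0.9260
3,HB2,En,0.866,0.9306
3,HB2,MR,0.8655,0.9303
3,HB2,MV,0.835,0.9138
3,HB2,FP,0.9078,0.9528
3,HB2,MW,,
3,Hb,En,0.9019,0.96497
3,Hb,MR,0.9221,0.9603
3,Hb,MV,0.9244,0.9615
3,Hb,FP,0.911,0.9545
3,Hb,MW,0.9651,0.9824
4,B1,En,0.9392,0.9691
4,B1,MR,0.9268,0.9627
4,B1,MV,0.9342,0.9665
4,B1,FP,0.9333,0.9661
4,B1,MW,0.9341,0.9665
4,B2,En,0.9702,0.9850
4,B2,MR,0.8849,0.9407
4,B2,MV,0.9161,0.9571
4,B2,FP,0.905,0.9513
4,B2,MW,0.8613,0.9281
4,HB1,En,0.9613,0.9805
4,HB1,MR,0.893,0.9450
4,HB1,MV,0.9382,0.9686
4,HB1,FP,0.9314,0.9651
4,HB1,MW,0.861,0.9279
4,HB2,En,0.8677,0.9315
4,HB2,MR,0.8668,0.9310
4,HB2,MV,0.8601,0.9274
4,HB2,FP,0.9093,0.9536
4,HB2,MW,,
4,Hb,En,0.9051,0.9514
4,Hb,MR,0.9257,0.9621
4,Hb,MV,0.9397,0.9694
4,Hb,FP,0.911,0.9544
4,Hb,MW,0.9651,0.9824
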