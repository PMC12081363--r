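{
 "name": "Tazobactam",
 "formula": "C10H12N4O5S",
 "vertices": [
  1,
  2,
  3,
  4,
  5,
  6,
  7,
  8,
  9,
  10,
  11,
  12,
  13,
  14,
  15,
  16,
  17,
  18,
  19,
  20
 ],
 "edges": [
  [
   1,
   2
  ],
  [
   2,
   3
  ],
  [
   2,
   9
  ],
  [
   2,
   18
  ],
  [
   3,
   4
  ],
  [
   4,
   5
  ],
  [
   4,
   8
  ],
  [
   5,
   6
  ],
  [
   6,
   7
  ],
  [
   7,
   8
  ],
  [
   9,
   10
  ],
  [
   9,
   13
  ],
  [
   10,
   11
  ],
  [
   10,
   12
  ],
  [
   13,
   14
  ],
  [
   13,
   17
  ],
  [
   14,
   15
  ],
  [
   14,
   16
  ],
  [
   16,
   17
  ],
  [
   17,
   18
  ],
  [
   18,
   19
  ],
  [
   18,
   20
  ]
 ]
}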