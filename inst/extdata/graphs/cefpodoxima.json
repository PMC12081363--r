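{
 "name": "Cefpodoxima",
 "formula": "C15H17N5O6S2",
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
  20,
  21,
  22,
  23,
  24,
  25,
  26,
  27,
  28
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
   3,
   4
  ],
  [
   4,
   5
  ],
  [
   4,
   11
  ],
  [
   5,
   6
  ],
  [
   5,
   10
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
   8,
   9
  ],
  [
   8,
   10
  ],
  [
   11,
   12
  ],
  [
   11,
   13
  ],
  [
   13,
   14
  ],
  [
   14,
   15
  ],
  [
   14,
   18
  ],
  [
   15,
   16
  ],
  [
   15,
   17
  ],
  [
   17,
   18
  ],
  [
   17,
   25
  ],
  [
   18,
   19
  ],
  [
   19,
   20
  ],
  [
   20,
   21
  ],
  [
   21,
   22
  ],
  [
   21,
   25
  ],
  [
   22,
   23
  ],
  [
   23,
   24
  ],
  [
   25,
   26
  ],
  [
   26,
   27
  ],
  [
   26,
   28
  ]
 ]
}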