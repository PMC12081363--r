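{
 "name": "Cefuroxime",
 "formula": "C16H16N4O8S",
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
  28,
  29
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
   10
  ],
  [
   5,
   6
  ],
  [
   5,
   9
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
   10,
   11
  ],
  [
   10,
   12
  ],
  [
   12,
   13
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
   16,
   26
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
   19,
   20
  ],
  [
   20,
   21
  ],
  [
   20,
   26
  ],
  [
   21,
   22
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
   23,
   25
  ],
  [
   26,
   27
  ],
  [
   27,
   28
  ],
  [
   27,
   29
  ]
 ]
}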