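{
 "name": "Moxifloxacin",
 "formula": "C21H24FN3O4",
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
   3,
   29
  ],
  [
   4,
   5
  ],
  [
   4,
   14
  ],
  [
   5,
   6
  ],
  [
   5,
   13
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
   7,
   12
  ],
  [
   8,
   9
  ],
  [
   9,
   10
  ],
  [
   10,
   11
  ],
  [
   11,
   12
  ],
  [
   12,
   13
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
   17,
   29
  ],
  [
   18,
   19
  ],
  [
   18,
   20
  ],
  [
   20,
   21
  ],
  [
   20,
   24
  ],
  [
   21,
   22
  ],
  [
   21,
   23
  ],
  [
   24,
   25
  ],
  [
   25,
   26
  ],
  [
   25,
   29
  ],
  [
   26,
   27
  ],
  [
   26,
   28
  ],
  [
   27,
   28
  ]
 ]
}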