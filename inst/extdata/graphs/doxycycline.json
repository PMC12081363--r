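{
 "name": "Doxycycline",
 "formula": "C22H24N2O8",
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
  29,
  30,
  31,
  32
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
   4
  ],
  [
   4,
   5
  ],
  [
   4,
   31
  ],
  [
   5,
   6
  ],
  [
   5,
   23
  ],
  [
   6,
   7
  ],
  [
   6,
   8
  ],
  [
   8,
   9
  ],
  [
   8,
   20
  ],
  [
   9,
   10
  ],
  [
   9,
   11
  ],
  [
   11,
   12
  ],
  [
   11,
   17
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
   14,
   15
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
   21,
   22
  ],
  [
   21,
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
   25,
   26
  ],
  [
   25,
   27
  ],
  [
   27,
   28
  ],
  [
   27,
   31
  ],
  [
   28,
   29
  ],
  [
   28,
   30
  ],
  [
   31,
   32
  ]
 ]
}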