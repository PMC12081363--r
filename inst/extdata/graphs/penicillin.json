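{
 "name": "Penicillin",
 "formula": "C16H18N2O4S",
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
  23
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
   2,
   20
  ],
  [
   4,
   5
  ],
  [
   5,
   6
  ],
  [
   5,
   19
  ],
  [
   6,
   7
  ],
  [
   6,
   17
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
   10,
   11
  ],
  [
   11,
   12
  ],
  [
   11,
   16
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
   17,
   18
  ],
  [
   17,
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
   23
  ]
 ]
}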