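{
 "name": "Cefaclor",
 "formula": "C15H14ClN3O4S",
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
  24
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
   3,
   4
  ],
  [
   3,
   8
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
   12,
   16
  ],
  [
   13,
   14
  ],
  [
   13,
   15
  ],
  [
   15,
   16
  ],
  [
   15,
   21
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
   19,
   20
  ],
  [
   19,
   21
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
   22,
   24
  ]
 ]
}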