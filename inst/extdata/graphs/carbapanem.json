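{
 "name": "Carbapanem",
 "formula": "C18H29N3O5S",
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
  27
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
   15
  ],
  [
   3,
   4
  ],
  [
   3,
   10
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
   5,
   7
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
   15
  ],
  [
   12,
   13
  ],
  [
   12,
   14
  ],
  [
   15,
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
   27
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
   26
  ],
  [
   20,
   21
  ],
  [
   20,
   22
  ],
  [
   22,
   23
  ],
  [
   22,
   25
  ],
  [
   23,
   24
  ],
  [
   26,
   27
  ]
 ]
}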