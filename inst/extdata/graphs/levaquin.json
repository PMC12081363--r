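{
 "name": "Levaquin",
 "formula": "C18H20FN3O4",
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
  26
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
   25
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
   5,
   6
  ],
  [
   5,
   26
  ],
  [
   6,
   7
  ],
  [
   6,
   14
  ],
  [
   7,
   8
  ],
  [
   7,
   13
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
   10,
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
   26
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
  ]
 ]
}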