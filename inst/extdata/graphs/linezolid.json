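{
 "name": "Linezolid",
 "formula": "C16H20FN3O4",
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
   6,
   7
  ],
  [
   6,
   24
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
   22
  ],
  [
   9,
   10
  ],
  [
   9,
   21
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
   12,
   19
  ],
  [
   13,
   14
  ],
  [
   13,
   18
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
   16,
   17
  ],
  [
   17,
   18
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
   22,
   23
  ],
  [
   22,
   24
  ]
 ]
}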