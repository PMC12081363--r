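{
 "name": "Amoxicillin",
 "formula": "C16H19N3O5S",
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
  25
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
   22
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
   21
  ],
  [
   6,
   7
  ],
  [
   6,
   19
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
   10,
   12
  ],
  [
   12,
   13
  ],
  [
   12,
   18
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
   23,
   24
  ],
  [
   23,
   25
  ]
 ]
}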