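{
 "name": "Unasyn",
 "formula": "C16H19N3O4S",
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
   11
  ],
  [
   2,
   11
  ],
  [
   3,
   13
  ],
  [
   4,
   17
  ],
  [
   5,
   18
  ],
  [
   6,
   16
  ],
  [
   7,
   17
  ],
  [
   8,
   10
  ],
  [
   9,
   12
  ],
  [
   9,
   14
  ],
  [
   9,
   15
  ],
  [
   10,
   11
  ],
  [
   10,
   24
  ],
  [
   12,
   14
  ],
  [
   12,
   15
  ],
  [
   13,
   17
  ],
  [
   13,
   21
  ],
  [
   14,
   19
  ],
  [
   15,
   18
  ],
  [
   16,
   18
  ],
  [
   16,
   21
  ],
  [
   17,
   24
  ],
  [
   18,
   20
  ],
  [
   19,
   25
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
   23,
   25
  ]
 ],
 "synthetic": true
}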