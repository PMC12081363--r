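{
 "name": "Avibactam",
 "formula": "C7H11N3O6S",
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
  18
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
   14
  ],
  [
   4,
   14
  ],
  [
   5,
   9
  ],
  [
   6,
   13
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
   8,
   12
  ],
  [
   8,
   18
  ],
  [
   9,
   10
  ],
  [
   10,
   12
  ],
  [
   10,
   16
  ],
  [
   11,
   16
  ],
  [
   12,
   14
  ],
  [
   13,
   15
  ],
  [
   13,
   18
  ],
  [
   14,
   17
  ],
  [
   15,
   17
  ]
 ],
 "synthetic": true
}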