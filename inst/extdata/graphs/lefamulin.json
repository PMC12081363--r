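{
 "name": "Lefamulin",
 "formula": "C28H45NO5S",
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
  32,
  33,
  34,
  35
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
   12
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
   10
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
   14
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
   16,
   18
  ],
  [
   16,
   20
  ],
  [
   18,
   19
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
   24,
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
   28,
   29
  ],
  [
   29,
   30
  ],
  [
   29,
   34
  ],
  [
   30,
   31
  ],
  [
   31,
   32
  ],
  [
   32,
   33
  ],
  [
   33,
   34
  ],
  [
   34,
   35
  ]
 ]
}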