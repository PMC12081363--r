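{
 "name": "Ceftriaxone",
 "formula": "C18H18N8O7S3",
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
  35,
  36
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
   3,
   4
  ],
  [
   4,
   5
  ],
  [
   4,
   11
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
   11,
   12
  ],
  [
   11,
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
   14,
   18
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
   17,
   33
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
   20,
   21
  ],
  [
   21,
   22
  ],
  [
   21,
   33
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
   24,
   25
  ],
  [
   24,
   31
  ],
  [
   25,
   26
  ],
  [
   26,
   27
  ],
  [
   26,
   28
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
   30,
   31
  ],
  [
   31,
   32
  ],
  [
   33,
   34
  ],
  [
   34,
   35
  ],
  [
   34,
   36
  ]
 ]
}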