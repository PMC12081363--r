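{
 "name": "Omadacycline",
 "formula": "C29H40N4O7",
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
  36,
  37,
  38,
  39,
  40
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
   4,
   17
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
   14
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
   10,
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
   16,
   39
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
   38
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
   34
  ],
  [
   22,
   23
  ],
  [
   22,
   26
  ],
  [
   23,
   24
  ],
  [
   23,
   25
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
   32
  ],
  [
   29,
   30
  ],
  [
   29,
   31
  ],
  [
   32,
   33
  ],
  [
   32,
   34
  ],
  [
   34,
   35
  ],
  [
   34,
   36
  ],
  [
   36,
   37
  ],
  [
   36,
   38
  ],
  [
   38,
   39
  ],
  [
   39,
   40
  ]
 ]
}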