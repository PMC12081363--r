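{
 "name": "Ceftabiprole",
 "formula": "C20H22N8O6S2",
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
   3,
   31
  ],
  [
   4,
   5
  ],
  [
   4,
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
   7,
   11
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
   27
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
   13,
   14
  ],
  [
   14,
   15
  ],
  [
   14,
   27
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
   16,
   25
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
   25
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
   22,
   23
  ],
  [
   23,
   24
  ],
  [
   25,
   26
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
   28,
   30
  ],
  [
   31,
   32
  ],
  [
   31,
   36
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
   33,
   35
  ],
  [
   35,
   36
  ]
 ]
}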