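{
 "name": "Clarithromycin",
 "formula": "C38H69NO13",
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
  40,
  41,
  42,
  43,
  44,
  45,
  46,
  47,
  48,
  49,
  50,
  51,
  52
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
   50
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
   7
  ],
  [
   7,
   8
  ],
  [
   7,
   9
  ],
  [
   9,
   10
  ],
  [
   9,
   22
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
   21
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
   13,
   15
  ],
  [
   13,
   17
  ],
  [
   15,
   16
  ],
  [
   17,
   18
  ],
  [
   17,
   19
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
  ],
  [
   24,
   25
  ],
  [
   24,
   37
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
   35
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
   30,
   31
  ],
  [
   31,
   32
  ],
  [
   31,
   35
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
   35,
   36
  ],
  [
   37,
   38
  ],
  [
   37,
   39
  ],
  [
   37,
   41
  ],
  [
   39,
   40
  ],
  [
   41,
   42
  ],
  [
   42,
   43
  ],
  [
   42,
   44
  ],
  [
   44,
   45
  ],
  [
   44,
   46
  ],
  [
   46,
   47
  ],
  [
   46,
   48
  ],
  [
   48,
   49
  ],
  [
   48,
   50
  ],
  [
   50,
   51
  ],
  [
   50,
   52
  ]
 ]
}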