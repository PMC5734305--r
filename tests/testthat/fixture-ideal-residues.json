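{
 "LEU": {
  "N": [
   -1.661,
   0.627,
   -0.406
  ],
  "CA": [
   -0.205,
   0.441,
   -0.467
  ],
  "C": [
   0.18,
   -0.055,
   -1.836
  ],
  "O": [
   -0.591,
   -0.731,
   -2.474
  ],
  "CB": [
   0.221,
   -0.583,
   0.585
  ],
  "CG": [
   -0.17,
   -0.079,
   1.976
  ],
  "CD1": [
   0.256,
   -1.104,
   3.029
  ],
  "CD2": [
   0.526,
   1.254,
   2.25
  ]
 },
 "ILE": {
  "N": [
   -1.944,
   0.335,
   -0.343
  ],
  "CA": [
   -0.487,
   0.519,
   -0.369
  ],
  "C": [
   0.066,
   -0.032,
   -1.657
  ],
  "O": [
   -0.484,
   -0.958,
   -2.203
  ],
  "CB": [
   0.14,
   -0.219,
   0.814
  ],
  "CG1": [
   -0.421,
   0.341,
   2.122
  ],
  "CG2": [
   1.658,
   -0.027,
   0.788
  ],
  "CD1": [
   0.206,
   -0.397,
   3.305
  ]
 },
 "HYP": {
  "N": [
   0.168,
   1.36,
   -0.282
  ],
  "CA": [
   -0.384,
   -0.003,
   -0.493
  ],
  "C": [
   -1.811,
   -0.072,
   -0.013
  ],
  "O": [
   -2.233,
   0.764,
   0.75
  ],
  "CB": [
   0.515,
   -0.924,
   0.359
  ],
  "CG": [
   1.847,
   -0.159,
   0.505
  ],
  "CD": [
   1.64,
   1.159,
   -0.271
  ],
  "OD1": [
   2.917,
   -0.911,
   -0.071
  ]
 },
 "ARG": {
  "N": [
   -0.469,
   1.11,
   -0.993
  ],
  "CA": [
   0.004,
   2.294,
   -1.708
  ],
  "C": [
   -0.907,
   2.521,
   -2.901
  ],
  "O": [
   -1.827,
   1.789,
   -3.242
  ],
  "CB": [
   1.475,
   2.15,
   -2.127
  ],
  "CG": [
   1.745,
   1.017,
   -3.13
  ],
  "CD": [
   3.21,
   0.954,
   -3.557
  ],
  "NE": [
   4.071,
   0.726,
   -2.421
  ],
  "CZ": [
   5.469,
   0.624,
   -2.528
  ],
  "NH1": [
   6.259,
   0.404,
   -1.405
  ],
  "NH2": [
   6.078,
   0.744,
   -3.773
  ]
 },
 "VAL": {
  "N": [
   1.564,
   -0.642,
   0.454
  ],
  "CA": [
   0.145,
   -0.698,
   0.079
  ],
  "C": [
   -0.037,
   -0.093,
   -1.288
  ],
  "O": [
   0.703,
   0.784,
   -1.664
  ],
  "CB": [
   -0.682,
   0.086,
   1.098
  ],
  "CG1": [
   -0.497,
   -0.528,
   2.487
  ],
  "CG2": [
   -0.218,
   1.543,
   1.119
  ]
 }
}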