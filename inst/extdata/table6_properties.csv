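drug,En,MW,MV,FP,MR
Linezolid,87.5 ± 3,337.346,259 ± 3,307.9 ± 30.1,83 ± 0.3
Omadacycline,127.6 ± 3,556.651,398.4 ± 5,460.4 ± 34.3,147.5 ± 0.4
Moxifloxacin,98.8 ± 3,401.431,285 ± 3,338.7 ± 31.5,101.8 ± 0.3
Ceftriaxone,,554.580,281.7 ± 7,,130 ± 0.5
Unasyn,105.4 ± 3,349.4,239.3 ± 5,367.4 ± 31.5,89.9 ± 4
Lefamulin,105.1 ± 6,507.726,424.8 ± 5,327.9 ± 31.5,139.8 ± 0.4
Carbapanem,74.6 ± 6,153.135,99.3 ± 5,210.9 ± 22.9,35.7 ± 0.4
Cefuroxime,112.1 ± 3,424.385,241 ± 7,396.3 ± 35.7,96.7 ± 0.5
Cefaclor,109.5 ± 3,367.807,226.5 ± 5,385.2 ± 32.9,89.6 ± 0.4
Tetracycline,113 ± 3,444.435,266.3 ± 7,400.2 ± 35.7,106.9 ± 0.5
Amoxicillin,113.7 ± 3,365.404,236.2 ± 5,403.3 ± 32.9,91.5 ± 0.4
Ceftabiprole,,534.569,266.1 ± 7,,127.8 ± 0.5
Doxycycline,116.5 ± 3,444.435,271.1 ± 5,415 ± 32.9,109 ± 0.4
Avibactam,,265.244,143.1 ± 5,,54 ± 0.4
Tazobactam,108.6 ± 3,300.291,155.8 ± 7,381.4 ± 35.7,67.7 ± 0.5
Clarithromycin,133.4 ± 6,747.953,631.9 ± 5,440.9 ± 34.3,
Levaquin,,361.367,244 ± 75,,91.1 ± 70.4
Erythromycin,135.4 ± 6,733.927,607.2 ± 5,448.8 ± 34.3,189.2 ± 0.4
Cefpodoxima,,427.455,239.5 ± 7,,100.5 ± 0.5
Penicillin,344.390,,,,
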