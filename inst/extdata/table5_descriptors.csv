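drug,B1,B2,HB1,HB2,Hb
Linezolid,268,356,1452,2908,21.364
Omadacycline,520,850,3326,10566,33.453
Moxifloxacin,406,616,2536,6964,26.569
Ceftriaxone,440,634,2604,6406,31.675
Unasyn,312,474,1960,5498,20.6357
Lefamulin,453,716,2966,9504,30.213
Carbapanem,336,500,2058,4282,24.055
Cefuroxime,337,466,1919,4465,26.696
Cefaclor,342,440,1810,4724,21.392
Tetracycline,458,752,3122,10372,27.054
Amoxicillin,326,496,2052,5708,21.83
Ceftabiprole,454,658,2698,6678,37.376
Doxycycline,446,710,2934,8834,27.69
Avibactam,224,340,1414,3852,14.06
Tazobactam,280,454,1886,6354,16.911
Clarithromycin,626,944,3912,10880,43.984
Levaquin,322,462,1890,4386,22.462
Erythromycin,598,886,3666,9678,46.817
Cefpodoxima,344,516,2124,6184,26.907
Penicillin,298,448,1852,5116,19.905
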