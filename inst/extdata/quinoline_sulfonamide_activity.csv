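compound_id,dpph_percent,sod_ic50_uM,mw,B. cereus,S. aureus ATCC 29213,S. aureus ATCC 25923,S. epidermidis ATCC 12228,M. luteus ATCC 10240,B. subtilis ATCC 6633,MRSA JCSC 4788,MRSA N315,MRSA JCSC 3063,P. shigelloides,L. monocytogenes,A. hydrophila,E. coli ATCC 25922,S. typhimurium ATCC 13311,P. stutzeri ATCC 17587,S. enteritidis,M. morganii,C. freundii
3,10.09,153.56,302.35,128,64,64,,64,<=4,64,8,<=4,,,,,,,,,
4,9.26,,318.80,<=4,64,<=4,64,<=4,<=4,<=4,<=4,<=4,16,16,,,,,,,
5,7.74,212.58,363.25,,,,,,<=4,,8,<=4,,,,,,,,,
6,12.06,247.39,352.36,<=4,,<=4,,,<=4,<=4,<=4,<=4,<=4,<=4,,,,,,,
7,9.79,250.37,326.40,,,,,,,,,,,,,,,,,,
8,12.53,96.07,309.37,<=4,,<=4,,,<=4,,<=4,<=4,,,128,,,,,,
9,36.49,254.58,329.36,,,,,,,,,,,,,,,,,,
10,19.06,448.75,329.36,128,,,,,,,,,,,,,,,,,
11,22.43,530.93,340.48,,,,,,,,,,,,,,,,,,
12,13.88,83.34,334.42,,,,,,,,,,,,256,256,256,256,256,256,256
13,17.33,600.81,362.46,,,,,,,,,,,,,,,,,,
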