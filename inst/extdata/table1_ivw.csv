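instrument,outcome,cases,or,ci_low,ci_high,pvalue
doherty5,breast_overall,122977,0.51,0.27,0.98,0.04
doherty5,breast_erpos,69501,0.45,0.20,1.01,0.054
doherty5,breast_erneg,21468,0.95,0.44,2.04,0.89
doherty5,crc_overall,52775,0.66,0.48,0.90,0.01
doherty5,crc_men,28207,0.79,0.50,1.23,0.29
doherty5,crc_women,24568,0.57,0.36,0.90,0.02
doherty5,colon,27817,0.64,0.44,0.94,0.02
doherty5,colon_proximal,12360,0.66,0.41,1.06,0.09
doherty5,colon_distal,14016,0.51,0.31,0.83,0.007
doherty5,rectal,13713,0.70,0.43,1.14,0.15
klimentidis10,breast_overall,122977,0.59,0.42,0.84,0.003
klimentidis10,breast_erpos,69501,0.53,0.35,0.82,0.004
klimentidis10,breast_erneg,21468,0.78,0.51,1.22,0.27
klimentidis10,crc_overall,52775,0.60,0.47,0.76,2.4e-5
klimentidis10,crc_men,28207,0.76,0.55,1.07,0.11
klimentidis10,crc_women,24568,0.49,0.35,0.68,3.0e-5
klimentidis10,colon,27817,0.56,0.42,0.73,4.4e-5
klimentidis10,colon_proximal,12360,0.60,0.42,0.86,0.005
klimentidis10,colon_distal,14016,0.45,0.31,0.64,1.7e-5
klimentidis10,rectal,13713,0.68,0.47,0.98,0.04
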