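41,F,f,f,f,f,f,f,f,f,f,f,f,f,f,f,t,1.3,t,2.5,t,125,t,1.14,t,109,f,?,SVHC,negative.|3733
23,M,f,f,f,f,f,f,f,f,f,f,f,f,f,f,t,4.1,t,2.0,t,102,t,0.91,t,120,f,?,other,negative.|1442
80,F,t,f,f,f,f,f,f,f,f,f,f,f,f,f,t,0.98,t,1.7,t,109,t,0.91,t,120,f,?,SVI,negative.|2965
55,F,f,f,f,f,f,f,t,f,f,f,f,f,f,f,t,0.16,t,4.8,t,180,t,1.9,t,150,f,?,STMW,sick.|21
67,M,f,f,f,f,f,f,f,f,f,f,f,f,f,f,t,2.2,?,?,t,131,t,1.02,t,128,f,?,other,negative.|88
34,F,f,f,f,f,f,f,f,f,t,f,f,f,f,f,t,1.9,t,2.9,t,141,t,1.30,t,108,f,?,SVI,negative.|510
78,M,f,f,f,f,f,f,f,f,f,f,f,f,f,f,?,?,t,2.1,t,118,t,1.08,t,110,f,?,other,negative.|77
49,F,f,f,f,t,f,f,f,f,f,f,f,f,f,f,t,3.3,t,1.5,t,98,t,0.99,t,99,f,?,SVHC,negative.|912
62,F,f,f,f,f,f,f,t,f,f,f,f,f,f,f,t,0.05,t,5.2,t,190,t,2.0,t,160,f,?,other,sick.|333
29,M,f,f,f,f,f,f,f,f,f,f,f,f,f,f,t,2.8,t,2.2,t,120,t,1.00,t,115,f,?,SVI,negative.|645
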