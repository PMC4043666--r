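compound,isomer,tr_30,tr_60,s_value,logkw
1,trans,27.97,45.94,4.64,3.60
1,cis,26.03,42.34,5.00,3.52
2,trans,29.45,48.28,4.04,3.39
2,cis,27.54,44.88,4.43,3.40
3,trans,29.35,48.37,4.30,3.56
3,cis,27.00,43.98,4.62,3.44
4,trans,29.37,48.51,4.41,3.64
5,trans,30.36,50.32,4.22,3.64
5,cis,28.50,46.83,4.47,3.56
6,trans,30.52,50.56,4.16,3.62
6,cis,28.06,45.89,4.40,3.45
7,trans,31.83,53.19,4.17,3.80
7,cis,29.97,49.67,4.37,3.69
8,trans,30.32,50.30,4.28,3.68
8,cis,29.10,47.99,4.41,3.60
9,trans,29.80,49.14,4.18,3.54
9,cis,27.75,45.36,4.49,3.46
10,trans,31.60,52.64,4.08,3.70
10,cis,28.95,47.73,4.46,3.62
11,trans,29.18,48.14,4.41,3.61
11,cis,27.52,45.08,4.70,3.57
12,trans,31.11,51.63,4.05,3.62
12,cis,28.80,47.32,4.35,3.52
13,trans,29.41,48.44,4.25,3.54
13,cis,27.91,45.69,4.51,3.50
14,trans,26.77,43.63,4.76,3.49
14,cis,25.34,40.95,4.99,3.41
15,trans,32.03,53.49,4.07,3.75
15,cis,29.67,49.09,4.37,3.66
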