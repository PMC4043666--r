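compound,pct_remaining_120min,pct_isomerization
1,53.51,5.84
2,75.13,6.52
3,76.13,7.76
4,62.86,0.00
5,79.95,5.84
6,83.88,3.50
7,60.90,5.53
8,58.23,5.25
9,96.03,9.28
10,90.80,7.79
11,98.97,1.50
12,95.11,5.41
13,95.33,2.66
14,74.88,0.00
15,99.40,4.93
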