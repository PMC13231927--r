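age_years,median_weight_kg
0.20,5.5
0.25,6.0
0.50,7.5
0.75,8.6
1.00,9.3
1.50,10.8
2.00,12.1
3.00,14.2
4.00,16.3
5.00,18.3
6.00,20.5
7.00,22.9
8.00,25.6
9.00,28.6
10.00,32.0
12.00,40.0
14.00,50.0
16.00,58.0
18.00,64.0
19.00,66.0
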