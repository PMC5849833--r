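energy_MeV,coefficient_pSv_cm2
1.0e-09,6.60
1.0e-08,9.00
2.5e-08,10.6
1.0e-07,12.9
2.0e-07,13.5
5.0e-07,13.6
1.0e-06,13.3
2.0e-06,12.9
5.0e-06,12.0
1.0e-05,11.3
2.0e-05,10.6
5.0e-05,9.90
1.0e-04,9.40
2.0e-04,8.90
5.0e-04,8.30
1.0e-03,7.90
2.0e-03,7.70
5.0e-03,8.00
1.0e-02,10.5
2.0e-02,16.6
3.0e-02,23.7
5.0e-02,41.1
7.0e-02,60.0
1.0e-01,88.0
1.5e-01,132
2.0e-01,170
3.0e-01,233
5.0e-01,322
7.0e-01,375
9.0e-01,400
1.0,416
1.2,425
2.0,420
3.0,412
4.0,408
5.0,405
6.0,400
7.0,405
8.0,409
9.0,420
10.0,440
12.0,480
14.0,520
15.0,540
16.0,555
18.0,570
20.0,600
30.0,515
50.0,400
75.0,330
100.0,285
125.0,260
150.0,245
175.0,250
201.0,260
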