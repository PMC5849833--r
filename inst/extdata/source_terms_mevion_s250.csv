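angle_bin_lo,angle_bin_hi,nozzle,water_phantom,fe_target
0,10,2.17E-15,1.64E-15,4.96E-15
10,20,1.24E-15,1.25E-15,4.67E-15
20,30,1.40E-15,1.35E-15,4.17E-15
30,40,1.45E-15,1.36E-15,3.62E-15
40,50,1.45E-15,1.26E-15,3.15E-15
50,60,1.51E-15,1.14E-15,2.82E-15
60,70,1.58E-15,1.02E-15,2.61E-15
70,80,1.50E-15,9.06E-16,2.42E-15
80,90,1.32E-15,7.92E-16,2.25E-15
90,100,1.01E-15,6.86E-16,2.17E-15
100,110,1.18E-15,5.97E-16,2.19E-15
110,120,1.25E-15,5.27E-16,2.22E-15
120,130,1.26E-15,4.59E-16,2.26E-15
130,140,1.25E-15,4.11E-16,2.32E-15
140,150,1.25E-15,3.66E-16,2.36E-15
150,160,1.25E-15,3.38E-16,2.42E-15
160,170,1.27E-15,3.31E-16,2.43E-15
170,180,1.24E-15,4.35E-16,2.44E-15
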