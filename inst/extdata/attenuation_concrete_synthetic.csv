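material,angle_bin_lo,angle_bin_hi,cyclotron,nozzle,phantom
concrete,0,10,0.5,0.45,0.42
concrete,10,20,0.496,0.447,0.417
concrete,20,30,0.49,0.441,0.412
concrete,30,40,0.48,0.433,0.404
concrete,40,50,0.468,0.422,0.394
concrete,50,60,0.453,0.409,0.382
concrete,60,70,0.436,0.395,0.368
concrete,70,80,0.418,0.38,0.353
concrete,80,90,0.4,0.363,0.338
concrete,90,100,0.38,0.347,0.322
concrete,100,110,0.362,0.33,0.307
concrete,110,120,0.344,0.315,0.292
concrete,120,130,0.327,0.301,0.278
concrete,130,140,0.312,0.288,0.266
concrete,140,150,0.3,0.277,0.256
concrete,150,160,0.29,0.269,0.248
concrete,160,170,0.284,0.263,0.243
concrete,170,180,0.28,0.26,0.24
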