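modality,age_group,index_kind,value
t1p5,g1,focus,0.174816
t1p5,g1,focus,0.155916
t1p5,g1,focus,0.07019
t1p5,g1,focus,0.084207
t1p5,g1,focus,0.12892
t1p5,g1,focus,0.14576
t1p5,g1,focus,0.222427
t1p5,g1,focus,0.275593
t1p5,g1,focus,0.315591
t3,g1,focus,0.001664
t3,g1,focus,0.001614
t3,g1,focus,0.000614
t3,g1,focus,0.000317
t3,g1,focus,0.000824
t3,g1,focus,0.001041
t3,g1,focus,0.001126
t3,g1,focus,0.002816
t3,g1,focus,0.003521
t1p5,g2,focus,0.261094
t1p5,g2,focus,0.076755
t1p5,g2,focus,0.002159
t1p5,g2,focus,0.010039
t1p5,g2,focus,0.018455
t1p5,g2,focus,0.053909
t1p5,g2,focus,0.095316
t1p5,g2,focus,0.100121
t1p5,g2,focus,0.239347
t3,g2,focus,0.013746
t3,g2,focus,0.001496
t3,g2,focus,0.000435
t3,g2,focus,5.16e-07
t3,g2,focus,3.76e-06
t3,g2,focus,0.00046
t3,g2,focus,0.000496
t3,g2,focus,0.004151
t3,g2,focus,0.01374
t1p5,g1,dispersion,245.8439
t1p5,g1,dispersion,241.6155
t1p5,g1,dispersion,222.8727
t1p5,g1,dispersion,183.2519
t1p5,g1,dispersion,152.8732
t1p5,g1,dispersion,63.68822
t1p5,g1,dispersion,62.51141
t1p5,g1,dispersion,52.44858
t1p5,g1,dispersion,48.76635
t3,g1,dispersion,3845.506
t3,g1,dispersion,3725.265
t3,g1,dispersion,3584.081
t3,g1,dispersion,3518.256
t3,g1,dispersion,3234.123
t3,g1,dispersion,1949.152
t3,g1,dispersion,1861.574
t3,g1,dispersion,1775.027
t3,g1,dispersion,1763.935
t1p5,g2,dispersion,272.6785
t1p5,g2,dispersion,208.9656
t1p5,g2,dispersion,207.59
t1p5,g2,dispersion,191.5476
t1p5,g2,dispersion,62.18858
t1p5,g2,dispersion,59.11231
t1p5,g2,dispersion,56.22063
t1p5,g2,dispersion,50.28433
t1p5,g2,dispersion,28.30434
t3,g2,dispersion,3919.487
t3,g2,dispersion,3684.96
t3,g2,dispersion,3605.269
t3,g2,dispersion,3396.184
t3,g2,dispersion,1969.419
t3,g2,dispersion,1557.758
t3,g2,dispersion,1547.73
t3,g2,dispersion,1542.073
t3,g2,dispersion,614.1261
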