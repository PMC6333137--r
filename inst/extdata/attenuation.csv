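# Mass attenuation coefficients (cm^2/g) on a NIST-style energy grid,
# rounded to ~3 significant figures, with bulk densities (g/cm^3).
# water/air/soft_tissue/bone/titanium follow NIST XCOM-tabulated values;
# gypsum (poured paste, density 1.85) and cerrobend (Bi/Pb/Sn/Cd
# 50/26.7/13.3/10 wt%, density 9.4) are mass-weighted elemental mixtures.
# Linear attenuation is mu = (mu/rho) * density; lookups between grid
# points use log-log interpolation.
material,density_g_cm3,energy_kev,mu_rho_cm2_g
air,0.001205,10,5.120
air,0.001205,15,1.614
air,0.001205,20,0.7779
air,0.001205,30,0.3538
air,0.001205,40,0.2485
air,0.001205,50,0.2080
air,0.001205,60,0.1875
air,0.001205,80,0.1662
air,0.001205,100,0.1541
air,0.001205,150,0.1356
water,1.000,10,5.329
water,1.000,15,1.673
water,1.000,20,0.8096
water,1.000,30,0.3756
water,1.000,40,0.2683
water,1.000,50,0.2269
water,1.000,60,0.2059
water,1.000,80,0.1837
water,1.000,100,0.1707
water,1.000,150,0.1505
soft_tissue,1.060,10,5.330
soft_tissue,1.060,15,1.693
soft_tissue,1.060,20,0.8205
soft_tissue,1.060,30,0.3783
soft_tissue,1.060,40,0.2688
soft_tissue,1.060,50,0.2264
soft_tissue,1.060,60,0.2048
soft_tissue,1.060,80,0.1823
soft_tissue,1.060,100,0.1693
soft_tissue,1.060,150,0.1492
bone,1.920,10,28.51
bone,1.920,15,9.032
bone,1.920,20,4.001
bone,1.920,30,1.331
bone,1.920,40,0.6655
bone,1.920,50,0.4242
bone,1.920,60,0.3148
bone,1.920,80,0.2229
bone,1.920,100,0.1855
bone,1.920,150,0.1480
gypsum,1.850,10,33.00
gypsum,1.850,15,10.40
gypsum,1.850,20,4.650
gypsum,1.850,30,1.535
gypsum,1.850,40,0.7550
gypsum,1.850,50,0.4700
gypsum,1.850,60,0.3410
gypsum,1.850,80,0.2320
gypsum,1.850,100,0.1900
gypsum,1.850,150,0.1490
titanium,4.506,10,110.7
titanium,4.506,15,35.87
titanium,4.506,20,15.76
titanium,4.506,30,4.972
titanium,4.506,40,2.214
titanium,4.506,50,1.213
titanium,4.506,60,0.7661
titanium,4.506,80,0.4052
titanium,4.506,100,0.2721
titanium,4.506,150,0.1649
cerrobend,9.400,10,126.7
cerrobend,9.400,15,91.00
cerrobend,9.400,20,66.05
cerrobend,9.400,30,23.87
cerrobend,9.400,40,11.33
cerrobend,9.400,50,6.350
cerrobend,9.400,60,3.980
cerrobend,9.400,80,1.930
cerrobend,9.400,100,4.120
cerrobend,9.400,150,1.510
steel,7.900,10,170.6
steel,7.900,15,57.08
steel,7.900,20,25.68
steel,7.900,30,8.176
steel,7.900,40,3.629
steel,7.900,50,1.958
steel,7.900,60,1.205
steel,7.900,80,0.5952
steel,7.900,100,0.3717
steel,7.900,150,0.1964
adipose,0.950,10,3.271
adipose,0.950,15,1.083
adipose,0.950,20,0.5877
adipose,0.950,30,0.3063
adipose,0.950,40,0.2396
adipose,0.950,50,0.2123
adipose,0.950,60,0.1974
adipose,0.950,80,0.1805
adipose,0.950,100,0.1694
adipose,0.950,150,0.1505
cocr,8.300,10,190.0
cocr,8.300,15,64.00
cocr,8.300,20,29.00
cocr,8.300,30,9.240
cocr,8.300,40,4.100
cocr,8.300,50,2.210
cocr,8.300,60,1.360
cocr,8.300,80,0.6720
cocr,8.300,100,0.4200
cocr,8.300,150,0.2220
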