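synthetic_basi.txt (synthetic fixture)
CYCLIC VOLTAMMETRY
Init E(mV) = -100
High E(mV) = 400

-0.1000,1.00068e-08
-0.0900,1.07426e-08
-0.0800,1.10422e-08
-0.0700,9.68066e-09
-0.0600,1.03226e-08
-0.0500,1.06851e-08
-0.0400,1.03203e-08
-0.0300,8.08512e-09
-0.0200,7.66032e-09
-0.0100,1.04841e-08
0.0000,1.11835e-08
0.0100,8.72579e-09
0.0200,1.06799e-08
0.0300,1.04607e-08
0.0400,1.13306e-08
0.0500,1.29627e-08
0.0600,1.42588e-08
0.0700,1.89256e-08
0.0800,3.25578e-08
0.0900,5.25256e-08
0.1000,8.43812e-08
0.1100,1.33012e-07
0.1200,2.01772e-07
0.1300,2.83647e-07
0.1400,3.73847e-07
0.1500,4.53544e-07
0.1600,5.07791e-07
0.1700,5.29308e-07
0.1800,5.07679e-07
0.1900,4.54324e-07
0.2000,3.72513e-07
0.2100,2.83096e-07
0.2200,2.01195e-07
0.2300,1.33559e-07
0.2400,8.23641e-08
0.2500,5.01418e-08
0.2600,2.97842e-08
0.2700,2.01682e-08
0.2800,1.61350e-08
0.2900,1.25011e-08
0.3000,1.05779e-08
0.3100,1.08053e-08
0.3200,1.12807e-08
0.3300,8.84204e-09
0.3400,9.39562e-09
0.3500,1.03885e-08
0.3600,8.60114e-09
0.3700,1.12326e-08
0.3800,1.00155e-08
0.3900,8.37904e-09
0.4000,9.33454e-09
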