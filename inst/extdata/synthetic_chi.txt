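Sept. 28, 2026   14:03:11
Cyclic Voltammetry
File: synthetic_chi.txt
Data Source:  Synthetic fixture (not instrument data)
Instrument Model:  CHI660-style ASCII layout
Init E (V) = 0.2
Final E (V) = -0.2
Scan Rate (V/s) = 0.1

Potential/V, Current/A
2.000e-01, 9.4309e-09
1.950e-01, 4.0548e-09
1.900e-01, 4.6586e-09
1.850e-01, 4.9316e-09
1.800e-01, 3.9440e-09
1.750e-01, 3.8291e-09
1.700e-01, 6.2222e-09
1.650e-01, 4.7745e-09
1.600e-01, 5.0287e-09
1.550e-01, 7.9343e-09
1.500e-01, 5.0340e-09
1.450e-01, 8.4216e-09
1.400e-01, 7.6144e-09
1.350e-01, 4.5191e-09
1.300e-01, 6.7081e-09
1.250e-01, 4.3769e-09
1.200e-01, 2.1085e-09
1.150e-01, 2.6916e-09
1.100e-01, 2.7206e-09
1.050e-01, 3.5583e-09
1.000e-01, 2.2931e-09
9.500e-02, 3.9485e-10
9.000e-02, -1.4642e-09
8.500e-02, -9.9438e-09
8.000e-02, -1.2963e-08
7.500e-02, -2.5429e-08
7.000e-02, -4.0912e-08
6.500e-02, -6.5161e-08
6.000e-02, -1.0187e-07
5.500e-02, -1.4861e-07
5.000e-02, -2.1416e-07
4.500e-02, -2.9673e-07
4.000e-02, -4.0596e-07
3.500e-02, -5.4014e-07
3.000e-02, -7.0095e-07
2.500e-02, -8.8668e-07
2.000e-02, -1.0915e-06
1.500e-02, -1.3173e-06
1.000e-02, -1.5452e-06
5.000e-03, -1.7694e-06
0.000e+00, -1.9762e-06
-5.000e-03, -2.1578e-06
-1.000e-02, -2.2946e-06
-1.500e-02, -2.3828e-06
-2.000e-02, -2.4112e-06
-2.500e-02, -2.3818e-06
-3.000e-02, -2.2928e-06
-3.500e-02, -2.1567e-06
-4.000e-02, -1.9791e-06
-4.500e-02, -1.7700e-06
-5.000e-02, -1.5471e-06
-5.500e-02, -1.3178e-06
-6.000e-02, -1.0949e-06
-6.500e-02, -8.8598e-07
-7.000e-02, -7.0223e-07
-7.500e-02, -5.4260e-07
-8.000e-02, -4.1207e-07
-8.500e-02, -3.0123e-07
-9.000e-02, -2.1681e-07
-9.500e-02, -1.5405e-07
-1.000e-01, -1.0508e-07
-1.050e-01, -7.0909e-08
-1.100e-01, -4.6625e-08
-1.150e-01, -3.0348e-08
-1.200e-01, -2.0394e-08
-1.250e-01, -1.2498e-08
-1.300e-01, -8.8694e-09
-1.350e-01, -5.8330e-09
-1.400e-01, -4.2755e-09
-1.450e-01, -4.3730e-09
-1.500e-01, -4.4232e-09
-1.550e-01, -6.3313e-09
-1.600e-01, -5.8742e-09
-1.650e-01, -6.3246e-09
-1.700e-01, -7.5953e-09
-1.750e-01, -7.2557e-09
-1.800e-01, -6.7413e-09
-1.850e-01, -6.3899e-09
-1.900e-01, -5.7951e-09
-1.950e-01, -2.2166e-09
-2.000e-01, -5.4864e-09
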