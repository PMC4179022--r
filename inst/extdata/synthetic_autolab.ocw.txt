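   -0.300000   3.722837e-10
   -0.295000   4.738998e-10
   -0.290000   2.354825e-10
   -0.285000   3.780365e-11
   -0.280000   5.712702e-10
   -0.275000   7.253014e-10
   -0.270000   9.801036e-10
   -0.265000   6.565716e-11
   -0.260000   2.294501e-09
   -0.255000   3.536488e-09
   -0.250000   2.203547e-09
   -0.245000   3.815452e-09
   -0.240000   4.241779e-09
   -0.235000   5.623101e-09
   -0.230000   5.576012e-09
   -0.225000   8.256531e-09
   -0.220000   7.746827e-09
   -0.215000   1.059648e-08
   -0.210000   1.322074e-08
   -0.205000   1.666668e-08
   -0.200000   2.025486e-08
   -0.195000   2.400593e-08
   -0.190000   2.831720e-08
   -0.185000   3.577199e-08
   -0.180000   4.179919e-08
   -0.175000   5.296149e-08
   -0.170000   6.387517e-08
   -0.165000   7.672438e-08
   -0.160000   9.158603e-08
   -0.155000   1.093845e-07
   -0.150000   1.314904e-07
   -0.145000   1.565522e-07
   -0.140000   1.852690e-07
   -0.135000   2.168864e-07
   -0.130000   2.558579e-07
   -0.125000   2.948422e-07
   -0.120000   3.419108e-07
   -0.115000   3.905643e-07
   -0.110000   4.416870e-07
   -0.105000   4.939388e-07
   -0.100000   5.512559e-07
   -0.095000   6.053682e-07
   -0.090000   6.584143e-07
   -0.085000   7.108053e-07
   -0.080000   7.601985e-07
   -0.075000   8.045697e-07
   -0.070000   8.454039e-07
   -0.065000   8.812282e-07
   -0.060000   9.160355e-07
   -0.055000   9.434892e-07
   -0.050000   9.695267e-07
   -0.045000   9.909674e-07
   -0.040000   1.008805e-06
   -0.035000   1.024856e-06
   -0.030000   1.036338e-06
   -0.025000   1.048188e-06
   -0.020000   1.057650e-06
   -0.015000   1.064691e-06
   -0.010000   1.071549e-06
   -0.005000   1.074761e-06
    0.000000   1.079515e-06
    0.005000   1.083881e-06
    0.010000   1.086824e-06
    0.015000   1.089439e-06
    0.020000   1.090964e-06
    0.025000   1.091927e-06
    0.030000   1.094354e-06
    0.035000   1.095326e-06
    0.040000   1.095069e-06
    0.045000   1.096395e-06
    0.050000   1.098158e-06
    0.055000   1.097047e-06
    0.060000   1.098009e-06
    0.065000   1.099049e-06
    0.070000   1.098138e-06
    0.075000   1.097725e-06
    0.080000   1.100124e-06
    0.085000   1.100306e-06
    0.090000   1.099441e-06
    0.095000   1.099826e-06
    0.100000   1.099706e-06
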