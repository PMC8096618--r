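# Definitive geomagnetic reference-field Gauss coefficients, epoch 2005.0
# Schmidt quasi-normalized, units nT; reference radius 6371.2 km.
# Truncated at degree 10 (higher-degree terms contribute < ~20 nT).
# gdot/hdot: linear secular-variation rates (nT/yr) valid 2005.0-2010.0,
# retained for degrees 1-3; higher-degree rates are a few nT/yr at most
# and are treated as zero over the validity window.
n,m,g,h,gdot,hdot
1,0,-29554.63,0.00,11.61,0.00
1,1,-1669.05,5077.99,16.53,-26.75
2,0,-2337.24,0.00,-11.76,0.00
2,1,3047.69,-2594.50,-4.27,-22.81
2,2,1657.76,-515.43,2.08,-12.06
3,0,1336.30,0.00,0.71,0.00
3,1,-2305.83,-198.86,-4.14,7.69
3,2,1246.39,269.72,-2.86,-3.59
3,3,672.51,-524.72,-7.76,-2.46
4,0,920.55,0.00,0.00,0.00
4,1,797.96,282.07,0.00,0.00
4,2,210.65,-225.23,0.00,0.00
4,3,-379.86,145.15,0.00,0.00
4,4,100.00,-305.36,0.00,0.00
5,0,-227.00,0.00,0.00,0.00
5,1,354.41,42.72,0.00,0.00
5,2,208.95,180.25,0.00,0.00
5,3,-136.54,-123.45,0.00,0.00
5,4,-168.05,-19.57,0.00,0.00
5,5,-13.55,103.85,0.00,0.00
6,0,73.60,0.00,0.00,0.00
6,1,69.56,-20.33,0.00,0.00
6,2,76.74,54.75,0.00,0.00
6,3,-151.34,63.63,0.00,0.00
6,4,-14.58,-63.53,0.00,0.00
6,5,14.58,0.24,0.00,0.00
6,6,-86.36,50.94,0.00,0.00
7,0,79.88,0.00,0.00,0.00
7,1,-74.46,-61.14,0.00,0.00
7,2,-1.65,-22.57,0.00,0.00
7,3,38.73,6.82,0.00,0.00
7,4,12.30,25.35,0.00,0.00
7,5,9.37,10.93,0.00,0.00
7,6,5.42,-26.32,0.00,0.00
7,7,1.94,-4.64,0.00,0.00
8,0,24.80,0.00,0.00,0.00
8,1,7.62,11.20,0.00,0.00
8,2,-11.73,-20.88,0.00,0.00
8,3,-6.88,9.83,0.00,0.00
8,4,-18.11,-19.71,0.00,0.00
8,5,10.17,16.22,0.00,0.00
8,6,9.36,7.61,0.00,0.00
8,7,-11.25,-12.76,0.00,0.00
8,8,-4.87,-0.06,0.00,0.00
9,0,5.58,0.00,0.00,0.00
9,1,9.76,-20.11,0.00,0.00
9,2,3.58,12.69,0.00,0.00
9,3,-6.94,12.67,0.00,0.00
9,4,5.01,-6.72,0.00,0.00
9,5,-10.76,-8.16,0.00,0.00
9,6,-1.25,8.10,0.00,0.00
9,7,8.76,2.92,0.00,0.00
9,8,-6.66,-7.73,0.00,0.00
9,9,-9.22,6.01,0.00,0.00
10,0,-2.17,0.00,0.00,0.00
10,1,-6.12,2.19,0.00,0.00
10,2,1.42,0.10,0.00,0.00
10,3,-2.35,4.46,0.00,0.00
10,4,-0.15,4.76,0.00,0.00
10,5,3.06,-6.58,0.00,0.00
10,6,0.29,-1.01,0.00,0.00
10,7,2.06,-3.47,0.00,0.00
10,8,3.77,-0.86,0.00,0.00
10,9,-0.21,-2.31,0.00,0.00
10,10,-2.09,-7.93,0.00,0.00
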