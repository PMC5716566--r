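# eyeplaque source model parameter file
name: Cs-1
dose_rate_constant: 1.0589999999999999
active_length: 0.40000000000000002
physical_length: 0.45000000000000001
half_life: 9.6890000000000001
[radial]
# r_cm  g
0.10000000000000001 0.96099999999999997
0.20000000000000001 0.96699999999999997
              0.25 0.97499999999999998
0.29999999999999999 0.97899999999999998
0.34999999999999998 0.98699999999999999
0.40000000000000002 0.98799999999999999
0.45000000000000001              0.997
               0.5              0.997
0.55000000000000004              0.999
0.59999999999999998 1.0009999999999999
0.65000000000000002 1.0029999999999999
0.69999999999999996 1.0009999999999999
              0.75 1.0049999999999999
0.80000000000000004 1.0009999999999999
0.84999999999999998                  1
0.90000000000000002              1.002
0.94999999999999996              1.002
                 1                  1
               1.2 0.99099999999999999
               1.3 0.98899999999999999
               1.5 0.97799999999999998
                 2 0.93400000000000005
               2.5               0.88
                 3 0.81799999999999995
               3.5              0.755
                 4 0.69099999999999995
               4.5               0.63
                 5 0.57099999999999995
               5.5 0.51500000000000001
                 6 0.46300000000000002
                 7               0.37
                 8 0.29299999999999998
                 9 0.23000000000000001
                10 0.17899999999999999
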