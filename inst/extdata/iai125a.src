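# eyeplaque source model parameter file
name: IAI-125A
dose_rate_constant: 0.97899999999999998
active_length: 0.29999999999999999
physical_length: 0.45000000000000001
half_life: 59.399999999999999
[radial]
# r_cm  g
0.10000000000000001 0.70999999999999996
0.20000000000000001 0.96099999999999997
              0.25              0.997
0.29999999999999999 1.0149999999999999
0.34999999999999998              1.024
0.40000000000000002              1.032
0.45000000000000001              1.038
               0.5              1.038
0.55000000000000004              1.034
0.59999999999999998              1.032
0.65000000000000002              1.032
0.69999999999999996              1.026
              0.75              1.024
0.80000000000000004              1.018
0.84999999999999998              1.016
0.90000000000000002              1.008
0.94999999999999996              0.999
                 1                  1
               1.2 0.97599999999999998
               1.3 0.95699999999999996
               1.5 0.93100000000000005
                 2 0.85099999999999998
               2.5 0.76900000000000002
                 3 0.68799999999999994
               3.5 0.61199999999999999
                 4 0.54100000000000004
               4.5 0.47499999999999998
                 5 0.41699999999999998
               5.5 0.36699999999999999
                 6              0.318
                 7 0.24199999999999999
                 8              0.183
                 9 0.13600000000000001
                10 0.10199999999999999
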