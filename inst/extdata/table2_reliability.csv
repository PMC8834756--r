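rater,time_s1,time_s2,correct_s1,correct_s2,kappa_total,kappa_total_low,kappa_total_high,kappa_male,kappa_male_low,kappa_male_high,kappa_female,kappa_female_low,kappa_female_high
1,20.0,13.8,88,83,0.87,0.72,1.00,0.93,0.77,1.00,0.68,0.34,1.00
2,17.5,13.8,79,88,0.80,0.61,0.99,0.83,0.58,1.00,0.69,0.38,1.00
3,13.1,12.9,83,71,0.82,0.67,0.97,0.74,0.52,0.96,1.00,1.00,1.00
4,14.6,12.0,79,83,0.87,0.71,1.00,0.78,0.68,0.89,0.78,0.39,1.00
5,19.6,17.1,67,83,0.75,0.56,0.94,0.75,0.50,0.99,0.69,0.38,1.00
6,16.0,14.0,83,83,0.78,0.60,0.97,0.71,0.48,0.95,0.85,0.63,1.00
7,13.2,12.6,83,71,0.67,0.45,0.90,0.58,0.27,0.88,0.80,0.44,1.00
8,11.3,10.6,79,88,0.75,0.57,0.94,0.71,0.42,0.99,0.79,0.52,1.00
9,12.5,11.3,75,75,0.83,0.67,1.00,0.70,0.41,0.99,1.00,1.00,1.00
10,15.0,13.1,67,79,0.67,0.45,0.88,0.69,0.43,0.95,0.59,0.29,0.90
11,24.6,18.3,71,67,0.82,0.64,0.99,0.91,0.75,1.00,0.63,0.38,0.88
12,21.7,10.3,67,88,0.81,0.66,0.97,0.89,0.74,1.00,0.63,0.38,0.88
13,26.3,19.8,83,83,0.77,0.58,0.95,0.83,0.61,1.00,0.65,0.43,0.87
14,12.8,10.4,75,75,0.82,0.65,0.99,0.83,0.62,1.00,0.76,0.42,1.00
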