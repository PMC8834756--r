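dichotomy,stratum,cutoff,sensitivity,specificity,youden
s_ml,total,13.0,1.00,0.00,0.00
s_ml,total,14.5,1.00,0.04,0.04
s_ml,total,15.5,0.98,0.32,0.30
s_ml,total,16.5,0.97,0.36,0.33
s_ml,total,17.5,0.97,0.57,0.54
s_ml,total,18.5,0.91,0.79,0.69
s_ml,total,19.5,0.81,0.93,0.74
s_ml,total,20.5,0.70,0.96,0.66
s_ml,total,21.5,0.50,1.00,0.49
s_ml,total,22.5,0.32,1.00,0.32
s_ml,total,23.5,0.16,1.00,0.16
s_ml,total,24.5,0.09,1.00,0.08
s_ml,total,25.5,0.02,1.00,0.02
s_ml,total,26.5,0.01,1.00,0.01
s_ml,total,28.0,0.00,1.00,0.00
s_ml,male,13.0,1.00,0.00,0.00
s_ml,male,14.5,1.00,0.05,0.05
s_ml,male,15.5,1.00,0.38,0.38
s_ml,male,16.5,1.00,0.57,0.43
s_ml,male,17.5,1.00,0.71,0.71
s_ml,male,18.5,0.98,0.81,0.79
s_ml,male,19.5,0.90,0.95,0.85
s_ml,male,20.5,0.76,0.95,0.71
s_ml,male,21.5,0.54,1.00,0.54
s_ml,male,22.5,0.32,1.00,0.32
s_ml,male,23.5,0.14,1.00,0.14
s_ml,male,24.5,0.08,1.00,0.08
s_ml,male,25.5,0.02,1.00,0.02
s_ml,male,26.5,0.00,1.00,0.00
s_ml,male,28.0,,,
s_ml,female,13.0,,,
s_ml,female,14.5,1.00,0.00,0.00
s_ml,female,15.5,0.96,0.10,0.10
s_ml,female,16.5,,,
s_ml,female,17.5,0.94,0.08,0.08
s_ml,female,18.5,0.83,0.71,0.54
s_ml,female,19.5,0.72,0.86,0.58
s_ml,female,20.5,0.63,1.00,0.63
s_ml,female,21.5,0.44,1.00,0.44
s_ml,female,22.5,0.33,1.00,0.33
s_ml,female,23.5,0.17,1.00,0.17
s_ml,female,24.5,0.09,1.00,0.09
s_ml,female,25.5,0.02,1.00,0.02
s_ml,female,26.5,,,
s_ml,female,28.0,0.00,1.00,0.00
sm_l,total,13.0,1.00,0.00,0.00
sm_l,total,14.5,1.00,0.01,0.01
sm_l,total,15.5,1.00,0.11,0.11
sm_l,total,16.5,1.00,0.13,0.13
sm_l,total,17.5,1.00,0.20,0.20
sm_l,total,18.5,1.00,0.32,0.32
sm_l,total,19.5,0.93,0.43,0.36
sm_l,total,20.5,0.89,0.55,0.44
sm_l,total,21.5,0.74,0.72,0.46
sm_l,total,22.5,0.59,0.84,0.44
sm_l,total,23.5,0.37,0.95,0.32
sm_l,total,24.5,0.19,0.97,0.15
sm_l,total,25.5,0.07,1.00,0.07
sm_l,total,26.5,0.04,1.00,0.04
sm_l,total,28.0,0.00,1.00,0.00
sm_l,male,13.0,1.00,0.00,0.00
sm_l,male,14.5,1.00,0.02,0.02
sm_l,male,15.5,1.00,0.13,0.13
sm_l,male,16.5,1.00,0.15,0.15
sm_l,male,17.5,1.00,0.25,0.25
sm_l,male,18.5,1.00,0.30,0.30
sm_l,male,19.5,1.00,0.41,0.41
sm_l,male,20.5,1.00,0.53,0.53
sm_l,male,21.5,0.90,0.70,0.61
sm_l,male,22.5,0.80,0.87,0.67
sm_l,male,23.5,0.50,0.97,0.47
sm_l,male,24.5,0.30,0.98,0.28
sm_l,male,25.5,0.10,1.00,0.10
sm_l,male,26.5,0.00,1.00,0.00
sm_l,male,28.0,,,
sm_l,female,13.0,,,
sm_l,female,14.5,1.00,0.00,0.00
sm_l,female,15.5,1.00,0.08,0.08
sm_l,female,16.5,,,
sm_l,female,17.5,1.00,0.11,0.11
sm_l,female,18.5,1.00,0.36,0.36
sm_l,female,19.5,0.88,0.47,0.36
sm_l,female,20.5,0.82,0.58,0.41
sm_l,female,21.5,0.65,0.75,0.40
sm_l,female,22.5,0.47,0.81,0.28
sm_l,female,23.5,0.29,0.92,0.21
sm_l,female,24.5,0.12,0.94,0.06
sm_l,female,25.5,0.06,1.00,0.06
sm_l,female,26.5,,,
sm_l,female,28.0,0.00,1.00,0.00
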