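session,stratum,kappa,ci_low,ci_high
1,total,0.50,0.47,0.53
1,male,0.43,0.39,0.47
1,female,0.56,0.46,0.68
2,total,0.54,0.51,0.57
2,male,0.50,0.27,0.57
2,female,0.57,0.51,0.73
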