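# 95% CI calibration constants for the truncated Q-Q reference-limit pipeline
# sd(limit estimate, working scale) = c_side / sqrt(n); see ?calibrate_ci95
version=1
seed=424242
reps=2000
sample_sizes=200,400,600,800,1000,1200,1400,1600,1800,2000
sd_lower=0.2002598623856811,0.1366670949212772,0.1099904020222091,0.0923031266189182,0.0823838071466043,0.0756008697379673,0.0708909428689963,0.0648599630529198,0.0647299334518310,0.0577690912748011
sd_upper=0.1982840237440908,0.1368824021928505,0.1097203495223150,0.0926176301587318,0.0822482536871665,0.0760144710017410,0.0711506310670323,0.0639168917186650,0.0628639595957711,0.0578702947426865
c_lower=2.72237989916661
c_upper=2.71011928811293
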