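map,parameter,group,mean,sd,n
A,gev,ASD,0.0909,0.0310,66
A,gev,TD,0.0967,0.0261,47
A,mean_duration_ms,ASD,71.58,4.804,66
A,mean_duration_ms,TD,71.91,3.985,47
A,coverage_pct,ASD,19.40,4.853,66
A,coverage_pct,TD,20.65,3.508,47
A,occurrence_per_s,ASD,2.357,0.4418,66
A,occurrence_per_s,TD,2.503,0.2859,47
B,gev,ASD,0.0983,0.0317,66
B,gev,TD,0.0796,0.0269,47
B,mean_duration_ms,ASD,72.48,4.748,66
B,mean_duration_ms,TD,68.86,3.500,47
B,coverage_pct,ASD,19.96,4.390,66
B,coverage_pct,TD,16.36,3.584,47
B,occurrence_per_s,ASD,2.398,0.3540,66
B,occurrence_per_s,TD,2.092,0.3333,47
C,gev,ASD,0.2249,0.0483,66
C,gev,TD,0.2317,0.0540,47
C,mean_duration_ms,ASD,84.12,5.810,66
C,mean_duration_ms,TD,83.87,6.313,47
C,coverage_pct,ASD,30.64,5.100,66
C,coverage_pct,TD,30.76,5.221,47
C,occurrence_per_s,ASD,3.081,0.3300,66
C,occurrence_per_s,TD,3.111,0.2675,47
D,gev,ASD,0.0747,0.0270,66
D,gev,TD,0.0751,0.0336,47
D,mean_duration_ms,ASD,70.01,4.171,66
D,mean_duration_ms,TD,69.30,4.183,47
D,coverage_pct,ASD,15.57,4.353,66
D,coverage_pct,TD,15.61,4.593,47
D,occurrence_per_s,ASD,1.951,0.4640,66
D,occurrence_per_s,TD,1.976,0.4438,47
E,gev,ASD,0.0627,0.0295,66
E,gev,TD,0.0756,0.0294,47
E,mean_duration_ms,ASD,68.27,4.808,66
E,mean_duration_ms,TD,69.57,5.057,47
E,coverage_pct,ASD,14.42,5.152,66
E,coverage_pct,TD,16.62,5.057,47
E,occurrence_per_s,ASD,1.846,0.5499,66
E,occurrence_per_s,TD,2.090,0.5178,47
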