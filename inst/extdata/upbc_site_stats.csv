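site,coral,dominant_direction,mean_speed,max_speed,lcf_orientation,coral_facing_mean,temp_mean,temp_min,temp_max,lcf_pct,dcf_pct,sc_pct,cr_pct,s_pct,pct_lt5,pct_lt10,pct_gt30,deployment_days
a,TRUE,185,31.3,114.2,SE,21.9,9.4,8.9,9.8,NA,NA,0,82,NA,1.6,8,46,27
b,TRUE,275,24.0,75.9,NE,21.5,9.2,9.1,9.4,33.8,28.3,NA,33.5,NA,5.4,28,37,4
c,TRUE,40,17.3,49.9,N,9.0,9.6,8.8,10.0,45,33.1,NA,21.9,NA,3.5,16.7,5,66
d,TRUE,325,25.4,66.3,NE,7.0,9.6,8.6,10.1,77.9,5.24,7.23,9.63,NA,1,6,31,67
e,TRUE,45,9.4,55.7,W,8.0,9.4,8.5,9.9,57.6,38.7,NA,2.96,0.65,11,36,2,66
f,FALSE,5,9.7,34.1,NA,NA,9.5,8.7,9.9,0,0,0,0,100,19,58,0.1,66
g,FALSE,175,18.2,56.4,NA,NA,8.6,7.7,12.3,0,0,0,0,100,4,15,7,66
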