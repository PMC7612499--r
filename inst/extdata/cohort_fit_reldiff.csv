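case,step,biomarker,rel_diff_pct
01,1,Pmax,3.0
01,1,dPdt_max,30.9
01,1,dPdt_min,26.7
01,1,PTD90,6.7
01,1,SV,10.4
01,2,Pmax,5.1
01,2,dPdt_max,3.7
01,2,dPdt_min,59.4
01,2,PTD90,2.1
01,2,SV,7.4
02,1,Pmax,0.0
02,1,dPdt_max,5.3
02,1,dPdt_min,2.5
02,1,PTD90,1.9
02,1,SV,6.8
02,2,Pmax,1.5
02,2,dPdt_max,18.5
02,2,dPdt_min,39.8
02,2,PTD90,1.2
02,2,SV,8.6
03,1,Pmax,5.7
03,1,dPdt_max,12.7
03,1,dPdt_min,5.4
03,1,PTD90,0.3
03,1,SV,0.1
03,2,Pmax,7.8
03,2,dPdt_max,28.7
03,2,dPdt_min,1.2
03,2,PTD90,4.1
03,2,SV,4.0
04,1,Pmax,2.7
04,1,dPdt_max,12.0
04,1,dPdt_min,0.9
04,1,PTD90,0.0
04,1,SV,20.9
04,2,Pmax,2.6
04,2,dPdt_max,5.7
04,2,dPdt_min,55.8
04,2,PTD90,4.1
04,2,SV,23.6
05,1,Pmax,10.1
05,1,dPdt_max,13.8
05,1,dPdt_min,5.7
05,1,PTD90,0.2
05,1,SV,11.5
05,2,Pmax,7.4
05,2,dPdt_max,22.9
05,2,dPdt_min,54.1
05,2,PTD90,0.5
05,2,SV,10.1
06,1,Pmax,8.7
06,1,dPdt_max,15.2
06,1,dPdt_min,6.3
06,1,PTD90,0.1
06,1,SV,12.5
06,2,Pmax,6.4
06,2,dPdt_max,6.8
06,2,dPdt_min,54.4
06,2,PTD90,4.1
06,2,SV,16.5
07,1,Pmax,7.7
07,1,dPdt_max,5.2
07,1,dPdt_min,6.3
07,1,PTD90,0.6
07,1,SV,7.6
07,2,Pmax,7.5
07,2,dPdt_max,71.2
07,2,dPdt_min,14.7
07,2,PTD90,4.3
07,2,SV,7.5
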