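time_s,position_cm,trial,block,event_type,consummatory
1.0,150,1,1,lick,FALSE
1.2,155,1,1,lick,FALSE
1.4,162,1,1,lick,FALSE
1.5,162,1,1,reward,FALSE
1.6,164,1,1,lick,TRUE
2.8,90,2,1,lick,FALSE
3.1,150,2,1,lick,FALSE
3.6,170,2,1,reward,FALSE
3.7,170,2,1,lick,TRUE
5.0,85,3,1,lick,FALSE
5.2,95,3,1,lick,FALSE
5.9,170,3,1,reward,FALSE
6.0,170,3,1,lick,TRUE
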