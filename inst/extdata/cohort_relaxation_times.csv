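subject,muscle,t1,t1_sd,t2l,t2l_sd,fl,t2s,t2s_sd,fs
1,GM,28.5,0.5,14.0,0.5,40,3.4,0.2,60
1,TA,29.4,1.0,12.5,0.3,40,3.1,0.2,60
1,S,28.9,0.3,14.2,0.3,40,2.5,0.8,60
2,GM,24.1,2.0,12.6,0.2,40,2.5,0.3,60
2,TA,25.4,0.3,13.7,0.8,40,3.0,0.4,60
2,S,26.0,0.2,12.7,0.3,55,4.0,3.0,45
3,GM,24.4,3.0,11.9,0.2,40,2.7,0.1,60
3,TA,26.4,0.4,12.2,0.2,45,2.6,0.3,55
3,S,27.7,0.8,11.0,0.2,40,2.6,0.1,60
4,GM,26.4,0.9,13.0,2.0,40,5.6,0.2,60
4,TA,29.0,2.0,12.7,0.5,40,3.9,2.0,60
4,S,30.1,0.9,13.4,2.0,45,4.5,0.6,55
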