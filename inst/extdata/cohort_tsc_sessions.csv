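subject,group,session,muscle,tsc,tsc_sd
1,healthy,M1,GM,20.2,0.8
1,healthy,M1,TA,13.4,0.7
1,healthy,M1,S,12.2,0.8
1,healthy,M2,GM,21.0,0.8
1,healthy,M2,TA,13.2,0.2
1,healthy,M2,S,12.7,0.3
1,healthy,M3,GM,20.0,0.3
1,healthy,M3,TA,13.2,0.2
1,healthy,M3,S,12.8,0.3
2,healthy,M1,GM,20.5,0.9
2,healthy,M1,TA,13.7,0.9
2,healthy,M1,S,12.9,0.9
2,healthy,M2,GM,20.8,0.4
2,healthy,M2,TA,14.0,0.8
2,healthy,M2,S,12.5,0.2
2,healthy,M3,GM,20.5,1.0
2,healthy,M3,TA,13.2,1.0
2,healthy,M3,S,12.7,1.0
3,healthy,M1,GM,19.9,0.2
3,healthy,M1,TA,14.6,1.0
3,healthy,M1,S,13.2,0.4
3,healthy,M2,GM,19.8,0.6
3,healthy,M2,TA,14.8,1.0
3,healthy,M2,S,13.0,1.0
3,healthy,M3,GM,19.6,2.0
3,healthy,M3,TA,14.6,0.8
3,healthy,M3,S,12.6,0.7
4,healthy,M1,GM,20.8,0.5
4,healthy,M1,TA,14.0,0.4
4,healthy,M1,S,12.5,0.9
4,healthy,M2,GM,20.5,1.0
4,healthy,M2,TA,14.5,0.6
4,healthy,M2,S,12.8,0.9
4,healthy,M3,GM,20.0,0.8
4,healthy,M3,TA,13.9,0.9
4,healthy,M3,S,13.1,0.7
5,healthy,M1,GM,20.0,0.8
5,healthy,M1,TA,14.9,0.2
5,healthy,M1,S,13.1,1.0
5,healthy,M2,GM,19.6,0.8
5,healthy,M2,TA,14.0,0.5
5,healthy,M2,S,12.2,0.2
5,healthy,M3,GM,19.4,1.0
5,healthy,M3,TA,13.5,0.5
5,healthy,M3,S,12.5,0.2
6,healthy,M1,GM,19.5,1.0
6,healthy,M1,TA,13.8,1.0
6,healthy,M1,S,13.9,0.5
6,healthy,M2,GM,20.0,2.0
6,healthy,M2,TA,13.1,0.1
6,healthy,M2,S,13.5,0.5
6,healthy,M3,GM,20.8,0.9
6,healthy,M3,TA,13.7,0.7
6,healthy,M3,S,13.4,0.4
7,healthy,M1,GM,19.9,0.9
7,healthy,M1,TA,13.5,0.5
7,healthy,M1,S,12.9,1.0
7,healthy,M2,GM,19.6,1.0
7,healthy,M2,TA,13.6,0.6
7,healthy,M2,S,12.7,0.7
7,healthy,M3,GM,19.7,0.6
7,healthy,M3,TA,13.3,0.6
7,healthy,M3,S,12.0,0.5
8,healthy,M1,GM,19.5,0.8
8,healthy,M1,TA,13.7,1.0
8,healthy,M1,S,12.1,0.4
8,healthy,M2,GM,19.5,0.9
8,healthy,M2,TA,13.0,0.7
8,healthy,M2,S,11.7,0.8
8,healthy,M3,GM,19.4,2.0
8,healthy,M3,TA,13.5,0.1
8,healthy,M3,S,11.1,0.3
9,healthy,M1,GM,19.0,0.2
9,healthy,M1,TA,14.1,0.7
9,healthy,M1,S,11.5,0.8
9,healthy,M2,GM,19.5,1.0
9,healthy,M2,TA,14.2,0.6
9,healthy,M2,S,12.6,0.2
9,healthy,M3,GM,19.0,0.5
9,healthy,M3,TA,13.5,0.4
9,healthy,M3,S,11.0,0.6
10,healthy,M1,GM,19.8,0.5
10,healthy,M1,TA,14.4,0.8
10,healthy,M1,S,12.2,0.2
10,healthy,M2,GM,19.0,0.7
10,healthy,M2,TA,14.0,0.2
10,healthy,M2,S,12.9,1.0
10,healthy,M3,GM,19.8,0.9
10,healthy,M3,TA,14.3,1.0
10,healthy,M3,S,12.8,1.0
11,addison,M1,GM,9.6,0.6
11,addison,M1,TA,7.7,0.7
11,addison,M1,S,7.2,0.8
12,addison,M1,GM,10.7,0.8
12,addison,M1,TA,8.0,0.8
12,addison,M1,S,7.1,1.0
13,addison,M1,GM,11.1,0.8
13,addison,M1,TA,9.0,1.0
13,addison,M1,S,7.1,2.0
14,addison,M1,GM,10.8,0.9
14,addison,M1,TA,8.8,2.0
14,addison,M1,S,7.4,0.5
15,addison,M1,GM,8.8,1.0
15,addison,M1,TA,8.7,0.9
15,addison,M1,S,7.3,0.4
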