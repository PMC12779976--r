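id,vt_2d,vt_auto,vt_r1,ri_2d,ri_auto,ri_r1
0,10.4,12.5,8.5,22.6,24.2,23.9
1,5.5,15.6,14.0,21.9,26.1,26.8
2,-1.7,0.5,0.8,15.2,16.9,16.4
3,19.1,11.2,9.7,20.9,22.7,23.4
4,8.4,10.6,12.1,16.5,23.0,21.7
5,NA,18.2,15.9,NA,28.8,30.3
6,12.3,14.0,14.1,21.4,24.0,26.8
7,5.0,9.6,13.4,21.8,22.8,21.4
8,14.6,15.6,14.8,23.9,24.5,26.2
9,11.3,14.2,13.5,21.6,20.0,22.0
10,15.2,17.1,17.2,18.9,24.6,24.1
11,NA,11.9,11.1,NA,23.7,22.6
12,9.5,14.2,12.5,22.0,24.3,23.1
13,0.1,19.3,12.4,25.1,28.6,27.8
14,NA,16.0,15.8,NA,28.2,25.5
15,14.0,14.6,14.6,23.8,23.2,25.3
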