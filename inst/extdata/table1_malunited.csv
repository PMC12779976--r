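id,vt_2d,vt_auto,vt_r1,vt_r2,ri_2d,ri_auto,ri_r1,ri_r2
0,-27.2,-30.0,-33.3,-30.5,13.9,15.2,14.6,16.0
1,-18.4,-13.0,-11.8,-11.2,14.6,15.0,18.1,16.9
2,-5.7,-6.6,-4.7,-4.5,9.0,10.0,10.8,10.0
3,-23.4,-14.4,-21.0,-25.0,5.5,7.2,5.7,5.7
4,23.0,27.3,26.6,30.4,31.6,32.9,33.4,33.7
5,-9.6,-13.4,-13.3,-11.4,22.2,24.9,23.8,25.4
6,-25.7,-23.8,-22.1,-24.5,19.6,22.3,21.8,20.6
7,-33.7,-38.2,-30.3,-34.8,12.4,10.3,14.9,9.6
8,-16.0,-10.3,-13.0,-11.8,20.9,21.7,22.4,21.6
9,-15.4,-11.5,-8.2,-6.6,18.0,16.5,17.1,16.6
10,-23.6,-25.1,-25.5,-27.5,14.7,17.2,19.9,16.2
11,NA,5.3,5.2,7.6,NA,9.7,11.0,10.3
12,-16.4,-13.4,-14.0,-10.2,25.4,28.0,25.4,25.6
13,-23.6,-18.6,-19.9,-15.3,16.0,21.1,18.8,18.8
14,-19.5,-14.8,-12.7,-10.9,26.8,23.5,22.2,24.8
15,3.3,4.6,1.0,0.3,5.0,11.7,11.6,10.2
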