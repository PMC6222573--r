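population,genotype,trait,god,z0,delta_m,cv_m2
G,A,AM,19.2,14.2,-0.0038,0.0000
G,A,Egg,19.2,6.2,-0.0037,0.0000
G,A,Size,19.2,3.1,-0.0001,0.0000
G,A,MaxV,19.2,49.8,-0.0438,0.0000
G,A,MeanV,19.2,10.3,-0.0400,0.0000
G,A,SDV,19.2,9.2,-0.0424,0.0000
G,B,AM,21.4,13.4,-0.0038,0.0000
G,B,Egg,21.4,4.9,0.0022,0.0000
G,B,Size,21.4,2.9,0.0005,0.0000
G,B,MaxV,21.4,25.4,-0.0275,0.0000
G,B,MeanV,21.4,4.7,-0.0257,0.0000
G,B,SDV,21.4,4.2,-0.0277,0.0000
G,C,AM,22.8,14.2,0.0030,0.0007
G,C,Egg,22.8,4.3,-0.0028,0.0053
G,C,Size,22.8,3.0,-0.0005,0.0000
G,C,MaxV,22.8,73.4,0.0006,4.9231
G,C,MeanV,22.8,16.7,0.0003,0.0048
G,C,SDV,22.8,13.7,-0.0015,0.0002
I,A,AM,24.8,14.8,-0.0013,0.0000
I,A,Egg,24.8,6.0,0.0017,0.0000
I,A,Size,24.8,2.9,0.0021,0.0000
I,A,MaxV,24.8,49.9,0.0085,0.0000
I,A,MeanV,24.8,7.8,0.0125,0.0000
I,A,SDV,24.8,9.2,0.0083,0.0000
I,B,AM,23.0,14.0,0.0007,0.0000
I,B,Egg,23.0,6.6,0.0033,0.0000
I,B,Size,23.0,2.9,0.0010,0.0000
I,B,MaxV,23.0,69.5,0.0048,0.0000
I,B,MeanV,23.0,14.9,0.0001,0.0000
I,B,SDV,23.0,14.3,0.0005,0.0000
I,C,AM,23.4,14.2,-0.0001,0.0000
I,C,Egg,23.4,6.5,0.0016,0.0000
I,C,Size,23.4,3.1,-0.0001,0.0000
I,C,MaxV,23.4,66.5,-0.0032,0.0000
I,C,MeanV,23.4,10.8,-0.0020,0.0000
I,C,SDV,23.4,11.7,-0.0003,0.0000
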