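dmu,te,pte,se,rts,sbm,order
1,1.000,1.000,1.000,CRS,1.000,8
2,0.910,0.930,0.979,DRS,0.437,30
3,1.000,1.000,1.000,CRS,1.000,11
4,1.000,1.000,1.000,CRS,1.000,3
5,0.913,1.000,0.913,DRS,0.714,21
6,1.000,1.000,1.000,CRS,1.000,15
7,1.000,1.000,1.000,CRS,1.000,4
8,1.000,1.000,1.000,CRS,1.000,13
9,1.000,1.000,1.000,CRS,1.000,7
10,1.000,1.000,1.000,CRS,1.000,2
11,1.000,1.000,1.000,CRS,1.000,16
12,0.634,0.669,0.946,DRS,0.363,32
13,0.985,0.986,0.999,DRS,0.757,20
14,1.000,1.000,1.000,CRS,1.000,5
15,1.000,1.000,1.000,CRS,1.000,14
16,0.958,1.000,0.958,IRS,0.577,25
17,1.000,1.000,1.000,CRS,1.000,12
18,0.993,0.998,0.996,IRS,0.679,22
19,0.990,0.991,0.999,IRS,0.886,18
20,0.948,0.958,0.990,IRS,0.670,23
21,0.912,0.919,0.992,CRS,0.472,29
22,0.883,1.000,0.883,DRS,0.570,26
23,0.922,1.000,0.922,DRS,0.812,19
24,1.000,1.000,1.000,CRS,1.000,10
25,0.958,1.000,0.958,DRS,0.567,27
26,1.000,1.000,1.000,CRS,1.000,1
27,0.968,0.999,0.969,IRS,0.485,28
28,1.000,1.000,1.000,CRS,1.000,17
29,0.873,0.887,0.985,DRS,0.422,31
30,0.980,0.980,1.000,CRS,0.607,24
31,1.000,1.000,1.000,CRS,1.000,9
32,1.000,1.000,1.000,CRS,1.000,6
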