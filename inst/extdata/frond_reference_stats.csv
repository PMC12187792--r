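element,n,min,max,mean,sd,rsd_pct,q1,median,q3,mad
C,35,428968,465741,449293,8952,2,445000,449229,454000,5064
N,35,20223,36254,25926,3643,14,23050,25889,28100,2615
Ag,35,0.008,0.103,0.017,0.016,91,0.011,0.014,0.018,0.004
Al,35,50.4,260,138,56.1,40,96.7,129,170,40.4
As,35,0.024,0.242,0.084,0.047,54,0.050,0.072,0.100,0.024
B,35,16.3,77.0,27.8,9.78,35,23.2,25.4,30.9,2.67
Ba,35,53.1,306,136,59.0,43,94.1,127,168,38.7
Be,35,0.004,0.302,0.043,0.064,147,0.012,0.018,0.049,0.010
Bi,35,0.001,0.025,0.004,0.004,95,0.002,0.003,0.006,0.001
Ca,35,4260,10763,6730,1701,25,5398,6248,8044,986
Cd,35,0.044,1.63,0.339,0.319,93,0.132,0.581,0.411,0.159
Ce,35,1.53,48.9,21.6,10.6,49,14.2,19.1,28.8,5.85
Co,35,0.036,0.833,0.171,0.153,90,0.082,0.114,0.222,0.045
Cr,35,0.307,1.85,0.489,0.261,53,0.375,0.421,0.509,0.075
Cs,35,0.016,20.0,1.88,3.68,193,0.179,0.415,2.47,0.319
Cu,35,5.04,15.3,9.24,2.22,23,7.92,9.02,10.0,1.12
Fe,35,72.0,300,127,44.3,34,102,112,142,14.8
Ga,35,0.084,0.421,0.225,0.083,36,0.167,0.208,0.251,0.043
Ge,35,0.086,0.488,0.220,0.091,41,0.162,0.208,0.243,0.041
Hg,35,0.021,0.110,0.045,0.025,54,0.027,0.036,0.054,0.010
K,35,14455,32592,23264,4723,20,19827,23762,27044,3390
La,35,1.62,72.4,18.4,13.0,70,11.6,15.6,20.8,4.58
Li,35,0.077,7.25,0.899,1.62,167,0.153,0.425,0.652,0.271
Mg,35,2023,6516,3318,1011,31,2752,3010,3804,425
Mn,35,34.1,931,146,157,112,88.35,104,142.0,22.8
Mo,35,0.098,1.65,0.388,0.356,96,0.166,0.234,0.443,0.104
Na,35,5.28,266,46.7,60.4,136,12.40,21.0,52.70,11.1
Nd,35,1.75,35.4,10.9,7.64,62,6.56,8.22,12.65,2.43
Ni,35,0.744,26.9,5.32,7.40,132,1.61,2.63,5.56,1.42
P,35,1102,3740,2012,643,31,1518,1913,2318,406
Pb,35,0.171,2.78,0.684,0.599,72,0.312,0.415,0.733,0.165
Pr,35,0.388,8.51,3.00,1.87,58,1.97,2.46,3.35,0.581
Rb,35,7.54,517,138,138,104,49.10,78.0,200,31.9
S,35,1339,2528,1832,264,15,1655,1852,1978,159
Sb,35,0.009,0.062,0.023,0.013,46,0.015,0.019,0.029,0.006
Se,35,0.34,0.498,0.190,0.115,58,0.104,0.159,0.249,0.061
Sn,35,0.029,0.122,0.056,0.024,38,0.041,0.046,0.068,0.010
Sr,35,9.67,64.2,28.7,14.3,50,16.70,25.4,34.15,9.18
Th,35,0.003,0.039,0.086,0.107,51,0.009,0.044,0.024,0.026
Tl,35,0.004,0.588,0.017,0.009,130,0.026,0.015,0.124,0.007
U,35,0.002,0.681,0.032,0.115,383,0.005,0.007,0.014,0.004
V,35,0.190,1.67,0.572,0.356,64,0.368,0.427,0.559,0.104
W,35,0.003,0.027,0.011,0.006,54,0.008,0.010,0.013,0.002
Y,35,0.207,35.1,3.23,5.95,70,0.988,1.57,2.975,0.953
Zn,35,19.7,56.7,28.0,8.10,30,23.15,26.4,28.95,3.27
Si,35,2973,13344,8386,2623,31,6312,8749,10116,2022
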