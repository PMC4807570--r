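element,energy_keV,mu_over_rho_cm2_g,edge_flag
H,10,0.385426,
H,11,0.383267,
H,12,0.381365,
H,13,0.379625,
H,14,0.377997,
H,15,0.376455,
H,16,0.374984,
H,16.5,0.374268,
H,17,0.373563,
H,17.2,0.373284,
H,18,0.37218,
H,19,0.370826,
H,20,0.369494,
H,22,0.366888,
H,25,0.363093,
C,10,2.373,
C,11,1.81114,
C,12,1.426,
C,13,1.15339,
C,14,0.9551,
C,15,0.807439,
C,16,0.695217,
C,16.5,0.649122,
C,17,0.608411,
C,17.2,0.593458,
C,18,0.540203,
C,19,0.485848,
C,20,0.441973,
C,22,0.376572,
C,25,0.313626,
N,10,3.8792,
N,11,2.9336,
N,12,2.28335,
N,13,1.82218,
N,14,1.48639,
N,15,1.23628,
N,16,1.04625,
N,16.5,0.968222,
N,17,0.899318,
N,17.2,0.874014,
N,18,0.783917,
N,19,0.692007,
N,20,0.61788,
N,22,0.507587,
N,25,0.401943,
O,10,5.95282,
O,11,4.48477,
O,12,3.47234,
O,13,2.75258,
O,14,2.22749,
O,15,1.83579,
O,16,1.53785,
O,16.5,1.41543,
O,17,1.30729,
O,17.2,1.26757,
O,18,1.1261,
O,19,0.981742,
O,20,0.865306,
O,22,0.692124,
O,25,0.526527,
Ca,10,93.4035,
Ca,11,71.5856,
Ca,12,56.0683,
Ca,13,44.7308,
Ca,14,36.255,
Ca,15,29.7922,
Ca,16,24.7787,
Ca,16.5,22.6904,
Ca,17,20.8307,
Ca,17.2,20.1438,
Ca,18,17.6801,
Ca,19,15.1359,
Ca,20,13.0592,
Ca,22,9.92513,
Ca,25,6.8707,
Fe,10,170.691,
Fe,11,132.283,
Fe,12,104.699,
Fe,13,84.3331,
Fe,14,68.9444,
Fe,15,57.0862,
Fe,16,47.7945,
Fe,16.5,43.8974,
Fe,17,40.4124,
Fe,17.2,39.1217,
Fe,18,34.4754,
Fe,19,29.6478,
Fe,20,25.683,
Fe,22,19.6514,
Fe,25,13.702,
Zn,10,233.09,
Zn,11,183.798,
Zn,12,146.927,
Zn,13,119.046,
Zn,14,97.71,
Zn,15,81.1847,
Zn,16,68.2234,
Zn,16.5,62.7814,
Zn,17,57.9092,
Zn,17.2,56.1029,
Zn,18,49.59,
Zn,19,42.7997,
Zn,20,37.1985,
Zn,22,28.6213,
Zn,25,20.083,
Y,10,68.712,
Y,11,52.932,
Y,12,41.7424,
Y,13,33.5724,
Y,14,27.4582,
Y,15,22.7847,
Y,16,19.1106,
Y,16.5,17.5776,
Y,17.037,16.1151,K-
Y,17.04,102.838,K+
Y,17.2,100.449,
Y,18,89.5884,
Y,19,78.1416,
Y,20,68.5545,
Y,22,53.5255,
Y,25,38.1305,
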