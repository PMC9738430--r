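tissue,state,magnification,parameter,mean,sd
brain,healthy,10x,af,0.99693,0.00677
brain,healthy,10x,fd,2.428,0.065
brain,healthy,10x,os,74.67,3.57
brain,healthy,10x,riv,0.0261,0.0019
brain,healthy,10x,sc,66.19,24.08
brain,tumoral,10x,af,0.99349,0.00748
brain,tumoral,10x,fd,2.179,0.155
brain,tumoral,10x,os,70.42,3.6
brain,tumoral,10x,riv,0.0302,0.0032
brain,tumoral,10x,sc,43.64,35.87
brain,healthy,20x,af,0.99886,0.00019
brain,healthy,20x,fd,2.604,0.065
brain,healthy,20x,os,39.16,1.47
brain,healthy,20x,riv,0.0148,0.0013
brain,healthy,20x,sc,17.18,6.24
brain,tumoral,20x,af,0.99891,0.00028
brain,tumoral,20x,fd,2.683,0.373
brain,tumoral,20x,os,40.87,4.96
brain,tumoral,20x,riv,0.0138,0.0048
brain,tumoral,20x,sc,15.97,8.98
brain,healthy,40x,af,0.99923,7e-05
brain,healthy,40x,fd,3.249,0.075
brain,healthy,40x,os,25.08,1.42
brain,healthy,40x,riv,0.0097,0.001
brain,healthy,40x,sc,10.6,2.94
brain,tumoral,40x,af,0.9994,0.00015
brain,tumoral,40x,fd,3.322,0.194
brain,tumoral,40x,os,26.38,2.83
brain,tumoral,40x,riv,0.0099,0.0031
brain,tumoral,40x,sc,16.03,12.24
ganglion,healthy,10x,af,0.99132,0.00988
ganglion,healthy,10x,fd,2.615,0.163
ganglion,healthy,10x,os,78.76,4.83
ganglion,healthy,10x,riv,0.0223,0.0042
ganglion,healthy,10x,sc,11.1,15.23
ganglion,tumoral,10x,af,0.96354,0.04785
ganglion,tumoral,10x,fd,2.218,0.255
ganglion,tumoral,10x,os,71.32,5.31
ganglion,tumoral,10x,riv,0.029,0.0043
ganglion,tumoral,10x,sc,16.37,26.96
ganglion,healthy,20x,af,0.99913,0.00017
ganglion,healthy,20x,fd,2.629,0.132
ganglion,healthy,20x,os,39.54,2.45
ganglion,healthy,20x,riv,0.0206,0.0021
ganglion,healthy,20x,sc,43.46,12.91
ganglion,tumoral,20x,af,0.99884,0.00036
ganglion,tumoral,20x,fd,2.665,0.416
ganglion,tumoral,20x,os,41.05,6.36
ganglion,tumoral,20x,riv,0.0144,0.0063
ganglion,tumoral,20x,sc,18.07,15.31
ganglion,healthy,40x,af,0.99938,0.00013
ganglion,healthy,40x,fd,3.275,0.233
ganglion,healthy,40x,os,26.26,4.62
ganglion,healthy,40x,riv,0.0108,0.0042
ganglion,healthy,40x,sc,18.39,11.12
ganglion,tumoral,40x,af,0.9993,2e-04
ganglion,tumoral,40x,fd,3.166,0.222
ganglion,tumoral,40x,os,24.51,2.75
ganglion,tumoral,40x,riv,0.0126,0.0035
ganglion,tumoral,40x,sc,22.74,16.1
kidney,healthy,10x,af,0.95906,0.14489
kidney,healthy,10x,fd,2.402,0.357
kidney,healthy,10x,os,81.18,26.2
kidney,healthy,10x,riv,0.0278,0.0058
kidney,healthy,10x,sc,25.77,26.86
kidney,tumoral,10x,af,0.99178,0.01074
kidney,tumoral,10x,fd,2.529,0.372
kidney,tumoral,10x,os,81.32,13.49
kidney,tumoral,10x,riv,0.0246,0.0065
kidney,tumoral,10x,sc,19.53,25.48
kidney,healthy,20x,af,0.99856,0.00147
kidney,healthy,20x,fd,2.553,0.487
kidney,healthy,20x,os,41.38,7.87
kidney,healthy,20x,riv,0.0168,0.0051
kidney,healthy,20x,sc,23.94,17.52
kidney,tumoral,20x,af,0.99897,0.00083
kidney,tumoral,20x,fd,2.647,0.384
kidney,tumoral,20x,os,41.44,6.16
kidney,tumoral,20x,riv,0.0194,0.004
kidney,tumoral,20x,sc,41.66,19.09
kidney,healthy,40x,af,0.99871,0.00252
kidney,healthy,40x,fd,3.215,0.273
kidney,healthy,40x,os,26.69,4.87
kidney,healthy,40x,riv,0.0104,0.0041
kidney,healthy,40x,sc,14.5,16.04
kidney,tumoral,40x,af,0.99937,3e-04
kidney,tumoral,40x,fd,3.172,0.32
kidney,tumoral,40x,os,25.67,4.62
kidney,tumoral,40x,riv,0.0136,0.0037
kidney,tumoral,40x,sc,30.45,16.89
liver,healthy,10x,af,0.98087,0.05989
liver,healthy,10x,fd,2.707,0.25
liver,healthy,10x,os,81.56,8.65
liver,healthy,10x,riv,0.0244,0.0059
liver,healthy,10x,sc,18.15,20.3
liver,tumoral,10x,af,0.88799,0.52312
liver,tumoral,10x,fd,2.525,0.363
liver,tumoral,10x,os,80.18,14.84
liver,tumoral,10x,riv,0.0267,0.0041
liver,tumoral,10x,sc,32.17,30.34
liver,healthy,20x,af,0.99653,0.00472
liver,healthy,20x,fd,2.67,0.285
liver,healthy,20x,os,40.9,3.45
liver,healthy,20x,riv,0.0217,0.0049
liver,healthy,20x,sc,36.57,29.09
liver,tumoral,20x,af,0.99802,0.00324
liver,tumoral,20x,fd,2.485,0.405
liver,tumoral,20x,os,39.1,5.57
liver,tumoral,20x,riv,0.0169,0.008
liver,tumoral,20x,sc,20.81,19.99
liver,healthy,40x,af,0.99932,3e-04
liver,healthy,40x,fd,3.194,0.207
liver,healthy,40x,os,25.4,2.54
liver,healthy,40x,riv,0.0124,0.005
liver,healthy,40x,sc,23.29,14.78
liver,tumoral,40x,af,0.99924,0.00038
liver,tumoral,40x,fd,3.129,0.309
liver,tumoral,40x,os,24.6,3.77
liver,tumoral,40x,riv,0.0128,0.0067
liver,tumoral,40x,sc,25.99,26.17
testicle,healthy,10x,af,0.93896,0.11773
testicle,healthy,10x,fd,2.661,0.254
testicle,healthy,10x,os,80.36,7.43
testicle,healthy,10x,riv,0.0201,0.0038
testicle,healthy,10x,sc,21.76,24.11
testicle,tumoral,10x,af,0.98946,0.02517
testicle,tumoral,10x,fd,2.558,0.311
testicle,tumoral,10x,os,78.1,7.05
testicle,tumoral,10x,riv,0.0238,0.0052
testicle,tumoral,10x,sc,33.17,37.61
testicle,healthy,20x,af,0.99882,0.00077
testicle,healthy,20x,fd,2.777,0.699
testicle,healthy,20x,os,45.26,11.38
testicle,healthy,20x,riv,0.0143,0.0083
testicle,healthy,20x,sc,16.99,15.3
testicle,tumoral,20x,af,0.99888,0.00178
testicle,tumoral,20x,fd,2.617,0.242
testicle,tumoral,20x,os,39.61,3.43
testicle,tumoral,20x,riv,0.0182,0.0021
testicle,tumoral,20x,sc,39.35,21.37
testicle,healthy,40x,af,0.99932,0.00043
testicle,healthy,40x,fd,3.123,0.547
testicle,healthy,40x,os,26.16,6.65
testicle,healthy,40x,riv,0.0156,0.0044
testicle,healthy,40x,sc,39.12,17.51
testicle,tumoral,40x,af,0.99943,2e-04
testicle,tumoral,40x,fd,3.144,0.207
testicle,tumoral,40x,os,24.2,2.52
testicle,tumoral,40x,riv,0.0127,0.002
testicle,tumoral,40x,sc,27.96,13.16
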