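year,rate_name,age_class,mean,se,n
2013,NI1,ASY,0.94,0.003,16
2013,NI1,SY,1,0,6
2013,NI2,pooled,0.2,0.01,15
2013,CS1,ASY,6.33,0.31,7
2013,CS1,SY,6.26,0.75,4
2013,CS2,ASY,4.64,0.3,1
2013,CS2,SY,,,0
2013,H,pooled,0.95,0.001,59
2013,NS1,ASY,0.19,0.12,15
2013,NS1,SY,0.55,0.12,6
2013,NS2,pooled,0.17,0.21,3
2013,S_chick,pooled,0.21,0.08,5
2013,S_juv,pooled,0.34,0.07,30
2013,S_annual,ASY,0.27,0.07,30
2013,S_annual,SY,0.2,0.07,16
2014,NI1,ASY,1,0,14
2014,NI1,SY,1,0,9
2014,NI2,pooled,0.52,0.01,23
2014,CS1,ASY,7,0.42,8
2014,CS1,SY,6,0.84,5
2014,CS2,ASY,5.31,0.3,5
2014,CS2,SY,4.61,0.4,1
2014,H,pooled,0.95,0.001,59
2014,NS1,ASY,0.23,0.11,12
2014,NS1,SY,0.49,0.14,8
2014,NS2,pooled,0.65,0.19,7
2014,S_chick,pooled,0.24,0.1,9
2014,S_juv,pooled,0.56,0.07,14
2014,S_annual,ASY,0.45,0.11,14
2014,S_annual,SY,0.37,0.11,8
2015,NI1,ASY,1,0,16
2015,NI1,SY,0.82,0.01,11
2015,NI2,pooled,0.25,0.01,16
2015,CS1,ASY,7.13,0.39,8
2015,CS1,SY,6.4,0.51,5
2015,CS2,ASY,5.44,0.3,1
2015,CS2,SY,,,0
2015,H,pooled,0.95,0.001,59
2015,NS1,ASY,0.37,0.12,15
2015,NS1,SY,0.57,0.12,9
2015,NS2,pooled,0.43,0.25,4
2015,S_chick,pooled,0.38,0.06,12
2015,S_juv,pooled,0.94,0.07,17
2015,S_annual,ASY,0.75,0.09,17
2015,S_annual,SY,0.68,0.11,13
2016,NI1,ASY,0.87,0.004,31
2016,NI1,SY,1,0,3
2016,NI2,pooled,0.15,0.01,26
2016,CS1,ASY,6.05,0.43,20
2016,CS1,SY,4.67,0.66,3
2016,CS2,ASY,4.36,0.3,2
2016,CS2,SY,,,0
2016,H,pooled,0.95,0.001,59
2016,NS1,ASY,0.29,0.07,27
2016,NS1,SY,0.5,0.15,3
2016,NS2,pooled,0.23,0.21,4
2016,S_chick,pooled,0.33,0.08,8
2016,S_juv,pooled,0.76,0.07,35
2016,S_annual,ASY,0.61,0.08,35
2016,S_annual,SY,0.53,0.1,13
2017,NI1,ASY,1,0,20
2017,NI1,SY,0.9,0.01,10
2017,NI2,pooled,0.59,0.01,17
2017,CS1,ASY,6.23,0.31,15
2017,CS1,SY,5.06,0.79,6
2017,CS2,ASY,4.54,0.3,7
2017,CS2,SY,3.67,0.4,3
2017,H,pooled,0.95,0.001,59
2017,NS1,ASY,0.42,0.13,19
2017,NS1,SY,0.53,0.1,8
2017,NS2,pooled,0.65,0.17,11
2017,S_chick,pooled,0.25,0.06,19
2017,S_juv,pooled,0.73,0.07,27
2017,S_annual,ASY,0.58,0.08,27
2017,S_annual,SY,0.5,0.1,17
2018,NI1,ASY,1,0,19
2018,NI1,SY,0.78,0.02,9
2018,NI2,pooled,0.36,0.02,14
2018,CS1,ASY,7.07,0.38,15
2018,CS1,SY,7.17,0.4,6
2018,CS2,ASY,5.38,0.3,2
2018,CS2,SY,,,0
2018,H,pooled,0.95,0.001,59
2018,NS1,ASY,0.36,0.1,18
2018,NS1,SY,0.58,0.14,5
2018,NS2,pooled,0.2,0.21,3
2018,S_chick,pooled,0.18,0.05,10
2018,S_juv,pooled,0.68,0.07,23
2018,S_annual,ASY,0.54,0.12,23
2018,S_annual,SY,0.46,0.1,6
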