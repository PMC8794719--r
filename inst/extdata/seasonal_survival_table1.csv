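year,season,age_class,mean,se,n
2013,breeding,ASY,0.55,0.07,30
2013,breeding,SY,0.47,0.09,16
2013,fall,ASY,0.55,0.07,30
2013,fall,SY,0.48,0.09,16
2013,winter,ASY,0.72,0.07,30
2013,winter,SY,0.67,0.09,16
2014,breeding,ASY,0.7,0.08,14
2014,breeding,SY,0.64,0.09,8
2014,fall,ASY,0.7,0.08,14
2014,fall,SY,0.64,0.09,8
2014,winter,ASY,0.83,0.06,14
2014,winter,SY,0.79,0.08,8
2015,breeding,ASY,0.87,0.05,17
2015,breeding,SY,0.83,0.06,13
2015,fall,ASY,0.87,0.05,17
2015,fall,SY,0.84,0.06,13
2015,winter,ASY,0.93,0.03,17
2015,winter,SY,0.91,0.04,13
2016,breeding,ASY,0.77,0.05,35
2016,breeding,SY,0.75,0.07,13
2016,fall,ASY,0.8,0.05,35
2016,fall,SY,0.75,0.06,13
2016,winter,ASY,0.89,0.04,35
2016,winter,SY,0.86,0.05,13
2017,breeding,ASY,0.77,0.05,27
2017,breeding,SY,0.73,0.07,17
2017,fall,ASY,0.78,0.05,27
2017,fall,SY,0.73,0.07,17
2017,winter,ASY,0.87,0.04,27
2017,winter,SY,0.84,0.05,17
2018,breeding,ASY,0.76,0.06,23
2018,breeding,SY,0.7,0.06,6
2018,fall,ASY,0.76,0.06,23
2018,fall,SY,0.71,0.08,6
2018,winter,ASY,0.86,0.05,23
2018,winter,SY,0.83,0.07,6
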