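subject,group,analyte,t_half_h,tmax_h,cmax_ng_ml,auc_0_12,auc_0_inf,aumc_0_inf
K1,2mgkg,tramadol,2.16,0.25,387.81,692.37,735.72,1929.46
K2,2mgkg,tramadol,3.58,0.5,503.74,1407.24,1504.19,5968.69
K3,4mgkg,tramadol,1.31,0.25,707.85,1066.38,1092.63,2029.25
K4,4mgkg,tramadol,3.53,0.5,843.13,1831.34,1958.58,7412.53
K5,4mgkg,tramadol,3.39,0.5,784.89,1507.24,1586.52,5229.76
K6,4mgkg,tramadol,2.39,0.25,728.85,2003.83,2093.69,7491.21
K1,2mgkg,M1,10.65,4,34.28,314.64,NA,NA
K2,2mgkg,M1,17.48,6,40.34,375.62,NA,NA
K3,4mgkg,M1,6.54,2,78.49,663.13,NA,NA
K4,4mgkg,M1,44.43,2,213.02,1335.17,NA,NA
K5,4mgkg,M1,23.74,8,83.49,799.08,NA,NA
K6,4mgkg,M1,25.64,6,95.15,882.90,NA,NA
K1,2mgkg,M2,8.42,4,50.36,470.93,NA,NA
K2,2mgkg,M2,8.00,4,75.39,687.51,NA,NA
K3,4mgkg,M2,4.37,1,99.47,651.00,NA,NA
K4,4mgkg,M2,8.23,2,162.35,1369.28,NA,NA
K5,4mgkg,M2,7.93,1,126.05,1041.88,NA,NA
K6,4mgkg,M2,6.93,4,143.47,1338.62,NA,NA
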