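condition,mean_ap,mean_ap_sd,mean_ml,mean_ml_sd,vel_ap,vel_ap_sd,vel_ml,vel_ml_sd,area95,area95_sd,mf_ap,mf_ap_sd,mf_ml,mf_ml_sd
1,3.71,1.02,1.33,0.65,17.31,3.46,9.22,1.21,148.99,102.53,0.92,0.29,1.49,0.56
2,4.17,1.90,1.61,0.82,18.71,4.03,9.82,1.65,190.46,152.39,0.96,0.37,1.39,0.64
3,3.90,1.26,1.73,1.41,18.89,3.22,9.56,1.74,209.30,239.64,0.96,0.27,1.38,0.63
4,5.50,1.57,3.15,1.08,29.73,7.56,15.40,3.93,530.12,314.76,1.03,0.32,0.96,0.28
5,5.92,1.83,3.24,1.19,32.96,8.19,15.88,3.30,574.78,342.18,1.06,0.27,0.96,0.29
6,5.92,2.16,3.12,1.19,29.59,7.61,14.39,3.02,569.81,450.65,0.98,0.30,0.91,0.25
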