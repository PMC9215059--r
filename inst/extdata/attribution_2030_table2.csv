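cancer,sex,pif_pct,pif_low,pif_high,cost_musd,attributable_musd
breast_any,F,2.70,2.08,3.32,620.39,16.77
colorectal,F,2.83,1.19,4.45,220.93,6.26
colorectal,M,3.58,1.92,5.17,228.91,8.19
endometrium,F,24.60,23.07,26.10,36.62,9.01
esophagus_any,F,2.28,2.06,2.49,9.76,0.22
esophagus_any,M,1.88,1.70,2.04,34.56,0.65
gallbladder,F,12.28,10.20,14.43,2.31,0.28
gallbladder,M,9.86,7.66,11.99,1.14,0.11
kidney,F,15.67,14.13,17.19,8.71,1.36
kidney,M,12.57,11.00,14.11,12.88,1.62
kidney,T,13.82,12.26,15.35,21.59,2.98
liver,F,21.61,19.01,24.20,5.48,1.18
liver,M,17.32,14.60,20.06,8.79,1.52
liver,T,18.97,16.30,21.65,14.27,2.71
mouth_pharynx_larynx,F,8.21,6.37,10.07,20.42,1.68
mouth_pharynx_larynx,M,6.57,4.68,8.40,92.01,6.04
ovary,F,3.17,1.46,4.87,61.78,1.96
pancreas,F,5.57,3.79,7.25,20.77,1.16
pancreas,M,5.72,3.79,7.58,20.08,1.15
prostate_any,M,0.91,0.49,1.31,352.87,3.21
stomach_any,F,0.47,0.38,0.56,26.58,0.13
stomach_any,M,0.56,0.43,0.70,47.55,0.27
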