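measure,dd_mean,dd_sd,dd_n,tr_mean,tr_sd,tr_n,published_t,published_df
Age,14.10,1.48,22,13.18,1.65,22,-1.94,42
IQ,10.59,1.78,22,13.70,2.82,22,4.38,42
IQ_Vocabulary,9.73,2.75,22,13.23,3.09,22,3.98,42
IQ_BlockDesign,11.82,2.04,22,14.18,3.65,22,2.65,42
TR_accuracy,-3.34,2.42,22,0.61,0.34,22,7.61,42
TR_speed,-2.55,1.01,22,0.16,0.65,22,10.55,42
SWR_accuracy,-3.41,2.63,22,0.27,0.56,22,6.42,42
SWR_speed,-3.66,2.16,22,0.04,0.57,22,7.75,42
SPWR_accuracy,-2.28,1.91,22,0.50,0.46,22,6.61,42
SPWR_speed,-3.38,2.42,22,0.26,0.64,22,6.82,42
SLFS,-1.15,0.72,NA,0.14,0.76,NA,5.72,41
SLBS,-0.71,0.75,NA,-0.07,0.89,NA,2.53,41
SDFS,-1.38,0.62,NA,-0.61,0.74,NA,3.68,41
SDBS,-0.56,0.47,NA,0.10,0.96,NA,2.84,41
SNWR,-1.66,2.71,22,1.18,1.40,22,4.38,42
DSM_IV_I,60.09,10.73,22,46.11,5.49,22,-5.43,42
DSM_IV_HI,49.20,7.96,NA,47.36,7.63,NA,-0.76,40
SES,58.84,19.16,NA,60.23,19.42,NA,0.56,39
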