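# Published within-laboratory reproducibility reference results: per-run
# normalized capacitance (mean and sample SD over three tissue replicates)
# at 17 kHz and 42 h post-exposure on an RhE model, for the 20 GD 220
# reference chemicals plus controls.
chemical_casrn,role,ghs_label,run,mean,sd
PBS,negative_control,NA,1,0.88,1.13
PBS,negative_control,NA,2,0.74,0.04
PBS,negative_control,NA,3,0.80,0.32
SDS-5pct,positive_control,NA,1,36.08,9.19
SDS-5pct,positive_control,NA,2,25.07,2.55
SDS-5pct,positive_control,NA,3,22.97,13.73
6940-78-9,test,NC,1,5.34,0.79
6940-78-9,test,NC,2,5.11,0.10
6940-78-9,test,NC,3,7.20,2.39
84-66-2,test,NC,1,1.00,0.14
84-66-2,test,NC,2,1.34,0.42
84-66-2,test,NC,3,1.23,0.29
86-87-3,test,NC,1,0.85,0.08
86-87-3,test,NC,2,1.90,0.28
86-87-3,test,NC,3,1.14,0.09
7493-74-5,test,NC,1,1.31,0.23
7493-74-5,test,NC,2,1.92,0.50
7493-74-5,test,NC,3,2.00,0.84
67-63-0,test,NC,1,2.87,0.93
67-63-0,test,NC,2,3.75,0.98
67-63-0,test,NC,3,4.33,1.33
3446-89-7,test,NC,1,3.59,1.78
3446-89-7,test,NC,2,4.67,2.62
3446-89-7,test,NC,3,4.35,2.24
112-61-8,test,NC,1,0.95,0.17
112-61-8,test,NC,2,1.21,0.12
112-61-8,test,NC,3,0.68,0.05
5870-93-9,test,NC,1,1.13,0.11
5870-93-9,test,NC,2,1.28,0.03
5870-93-9,test,NC,3,0.92,0.04
6259-76-3,test,NC,1,0.97,0.05
6259-76-3,test,NC,2,1.14,0.14
6259-76-3,test,NC,3,0.65,0.09
104-55-2,test,NC,1,4.02,0.27
104-55-2,test,NC,2,5.24,0.42
104-55-2,test,NC,3,6.57,1.28
112-30-1,test,CAT2,1,36.66,8.45
112-30-1,test,CAT2,2,41.67,2.66
112-30-1,test,CAT2,3,19.55,10.43
103-95-7,test,CAT2,1,15.69,6.58
103-95-7,test,CAT2,2,17.22,2.91
103-95-7,test,CAT2,3,8.73,4.88
111-25-1,test,CAT2,1,10.25,0.49
111-25-1,test,CAT2,2,10.23,0.89
111-25-1,test,CAT2,3,10.42,3.41
86604-75-3,test,CAT2,1,36.55,10.60
86604-75-3,test,CAT2,2,29.21,5.99
86604-75-3,test,CAT2,3,16.48,8.15
629-19-6,test,CAT2,1,9.50,0.70
629-19-6,test,CAT2,2,10.38,1.03
629-19-6,test,CAT2,3,5.79,2.30
1310-58-3,test,CAT2,1,20.26,4.76
1310-58-3,test,CAT2,2,35.58,14.10
1310-58-3,test,CAT2,3,23.98,8.76
7340-90-1,test,CAT2,1,9.63,0.69
7340-90-1,test,CAT2,2,12.80,0.78
7340-90-1,test,CAT2,3,16.88,16.24
5271-27-2,test,CAT2,1,8.81,2.09
5271-27-2,test,CAT2,2,11.64,4.63
5271-27-2,test,CAT2,3,19.64,13.67
111-71-7,test,CAT2,1,25.15,5.44
111-71-7,test,CAT2,2,42.30,4.93
111-71-7,test,CAT2,3,17.16,2.99
127-18-4,test,CAT2,1,19.89,3.37
127-18-4,test,CAT2,2,24.39,4.54
127-18-4,test,CAT2,3,16.35,3.21
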