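# Published normalized-capacitance reference results at 17 kHz on an RhE
# model for the 20 GD 220 reference chemicals plus controls (PBS negative,
# 5% SDS positive). Mean and sample SD over three runs at 2/24/42 h
# post-exposure. Truth labels are in vivo GHS: NC = No Category, CAT2 =
# Category 2.
chemical_casrn,role,ghs_label,time_h,mean,sd
PBS,negative_control,NA,2,0.96,0.02
PBS,negative_control,NA,24,0.87,0.10
PBS,negative_control,NA,42,0.81,0.07
SDS-5pct,positive_control,NA,2,21.66,4.94
SDS-5pct,positive_control,NA,24,22.50,1.24
SDS-5pct,positive_control,NA,42,28.04,7.04
6940-78-9,test,NC,2,1.17,0.22
6940-78-9,test,NC,24,3.17,0.48
6940-78-9,test,NC,42,5.88,1.15
84-66-2,test,NC,2,0.97,0.15
84-66-2,test,NC,24,1.07,0.10
84-66-2,test,NC,42,1.19,0.17
86-87-3,test,NC,2,1.26,0.09
86-87-3,test,NC,24,1.24,0.23
86-87-3,test,NC,42,1.30,0.34
7493-74-5,test,NC,2,1.08,0.14
7493-74-5,test,NC,24,1.17,0.23
7493-74-5,test,NC,42,1.74,0.38
67-63-0,test,NC,2,3.13,0.22
67-63-0,test,NC,24,2.89,0.20
67-63-0,test,NC,42,3.65,0.74
3446-89-7,test,NC,2,1.05,0.06
3446-89-7,test,NC,24,4.10,3.49
3446-89-7,test,NC,42,4.20,0.55
112-61-8,test,NC,2,1.04,0.08
112-61-8,test,NC,24,0.88,0.09
112-61-8,test,NC,42,0.95,0.27
5870-93-9,test,NC,2,1.17,0.14
5870-93-9,test,NC,24,1.07,0.18
5870-93-9,test,NC,42,1.11,0.18
6259-76-3,test,NC,2,1.00,0.15
6259-76-3,test,NC,24,0.96,0.13
6259-76-3,test,NC,42,0.92,0.25
104-55-2,test,NC,2,1.74,0.65
104-55-2,test,NC,24,2.83,0.27
104-55-2,test,NC,42,5.28,1.28
112-30-1,test,CAT2,2,2.55,1.00
112-30-1,test,CAT2,24,31.22,10.71
112-30-1,test,CAT2,42,33.29,12.00
103-95-7,test,CAT2,2,4.01,2.27
103-95-7,test,CAT2,24,10.94,3.70
103-95-7,test,CAT2,42,13.88,4.53
111-25-1,test,CAT2,2,4.41,2.27
111-25-1,test,CAT2,24,13.01,9.56
111-25-1,test,CAT2,42,10.30,0.10
86604-75-3,test,CAT2,2,33.16,16.72
86604-75-3,test,CAT2,24,34.00,18.61
86604-75-3,test,CAT2,42,27.41,10.15
629-19-6,test,CAT2,2,1.12,0.35
629-19-6,test,CAT2,24,8.31,2.24
629-19-6,test,CAT2,42,8.56,2.44
1310-58-3,test,CAT2,2,23.17,3.50
1310-58-3,test,CAT2,24,20.58,5.44
1310-58-3,test,CAT2,42,26.61,7.99
7340-90-1,test,CAT2,2,0.89,0.17
7340-90-1,test,CAT2,24,5.45,1.19
7340-90-1,test,CAT2,42,13.10,3.63
5271-27-2,test,CAT2,2,11.10,1.54
5271-27-2,test,CAT2,24,14.60,10.37
5271-27-2,test,CAT2,42,13.36,5.62
111-71-7,test,CAT2,2,27.52,9.31
111-71-7,test,CAT2,24,31.72,15.98
111-71-7,test,CAT2,42,28.20,12.85
127-18-4,test,CAT2,2,21.42,9.29
127-18-4,test,CAT2,24,19.26,10.44
127-18-4,test,CAT2,42,20.21,4.03
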