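# The 20 reference chemicals of OECD guidance document No. 220 used for
# assessing reproducibility and predictive capacity of RhE skin-irritation
# methods, with in vivo GHS labels.
number,name,chemical_casrn,ghs_label,physical_state
1,1-Bromo-4-chlorobutane,6940-78-9,NC,liquid
2,Diethyl phthalate,84-66-2,NC,liquid
3,Naphthalene acetic acid,86-87-3,NC,solid
4,Allylphenoxy-acetate,7493-74-5,NC,liquid
5,Isopropanol,67-63-0,NC,liquid
6,4-Methyl-thio-benzaldehyde,3446-89-7,NC,liquid
7,Methyl stearate,112-61-8,NC,solid
8,Heptyl butyrate,5870-93-9,NC,liquid
9,Heptyl salicylate,6259-76-3,NC,liquid
10,Cinnamaldehyde,104-55-2,NC,liquid
11,1-Decanol,112-30-1,CAT2,liquid
12,Cyclamen aldehyde,103-95-7,CAT2,liquid
13,1-Bromohexane,111-25-1,CAT2,liquid
14,"2-Chloromethyl-3,5-dimethyl-4-methoxypyridine HCl",86604-75-3,CAT2,solid
15,Di-n-propyl disulphide,629-19-6,CAT2,liquid
16,Potassium hydroxide (5% aq.),1310-58-3,CAT2,liquid
17,"Benzenethiol, 5-(1,1-dimethylethyl)-2-methyl",7340-90-1,CAT2,liquid
18,1-Methyl-3-phenyl-1-piperazine,5271-27-2,CAT2,solid
19,Heptanal,111-71-7,CAT2,liquid
20,Tetrachloroethylene,127-18-4,CAT2,liquid
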