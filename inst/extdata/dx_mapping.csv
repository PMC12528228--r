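name,abbreviation,code,prevalence
1st Degree AV Block,IAVB,270492004,3291
Atrial Fibrillation,AF,164889003,5062
Atrial Flutter,AFL,164890007,8509
Bradycardia,Brady,426627000,267
Bundle Branch Block,BBB,6374002,511
Complete Left Bundle Branch Block,CLBBB,733534002,218
Complete Right Bundle Branch Block,CRBBB,713427006,2015
Incomplete Right Bundle Branch Block,IRBBB,713426002,2306
Left Anterior Fascicular Block,LAnFB,445118002,2665
Left Axis Deviation,LAD,39732003,7952
Left Bundle Branch Block,LBBB,164909002,1260
Low QRS Voltage,LQRSV,251146004,1765
Nonspecific Intraventricular Conduction Disorder,NSIVCB,698252002,2101
Pacing Rhythm,PR,10370003,1694
Poor R Wave Progression,PRWP,365413008,656
Premature Atrial Contraction,PAC,284470004,2827
Premature Ventricular Contractions,PVC,427172004,1259
Prolonged PR Interval,LPR,164947007,393
Prolonged QT Interval,LQT,111975006,2152
Q Wave Abnormal,QAb,164917005,2261
Right Axis Deviation,RAD,47665007,1482
Right Bundle Branch Block,RBBB,59118001,2331
Sinus Arrhythmia,SA,427393009,4176
Sinus Bradycardia,SB,426177001,19303
Sinus Rhythm,NSR,426783006,30426
Sinus Tachycardia,STach,427084000,10261
Supraventricular Premature Beats,SVPB,63593006,267
T Wave Abnormal,TAb,164934002,12673
T Wave Inversion,TInv,59931005,4340
Ventricular Premature Beats,VPB,17338001,731
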