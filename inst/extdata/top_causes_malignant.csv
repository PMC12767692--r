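source_id,name,mean_causal_effect,evidence,opposite_polarity
1936,COPD,0.0152,Strong,FALSE
886,Respiratory tract primary malignancy,0.0136,Direct,FALSE
1940,Upper lobe primary malignancy,0.0095,Direct,FALSE
1198,Lower lobe primary malignancy,0.0067,Direct,FALSE
1622,Indeterminate Pulmonary Nodule,0.0067,Absent,FALSE
148,Hypertensive disorder,0.0044,Strong,FALSE
1872,Nicotine dependence,0.0034,Strong,FALSE
1452,Bladder primary malignancy,0.0034,Direct/Moderate,FALSE
638,Respiratory malignancy multiple locations,0.0025,Direct,FALSE
227,Pregnancy Elevated Glucose Complications,0.0022,Weak,FALSE
343,COPD ICS LABA,0.0021,Strong,TRUE
5,Tobacco dependence syndrome,0.0021,Strong,FALSE
760,Histoplasmosis,0.0021,Direct,TRUE
1066,Abnormal findings on lung imaging NOS,0.0020,Weak,FALSE
1616,Unrecorded Race URI,0.0020,Absent,TRUE
1158,Lovastatin,0.0020,Strong,TRUE
979,Lung Disorder NOS,0.0019,Absent,FALSE
1305,Age with elevated Hematocrit and other CV parameters,0.0018,Mixed,FALSE
467,Post-inflammatory vs idiopathic pulmonary fibrosis,0.0017,Strong,FALSE
7,Postpartum Pregnancy No Complications,0.0017,Absent,FALSE
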