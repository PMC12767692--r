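source_id,name,mean_causal_effect,evidence,opposite_polarity
1940,Upper lobe primary malignancy,-0.0129,Direct,TRUE
1198,Lower lobe primary malignancy,-0.0071,Direct,TRUE
886,Respiratory tract primary malignancy,-0.0061,Direct,TRUE
1616,Unrecorded Race URI,-0.0047,Absent,FALSE
227,Pregnancy Elevated Glucose Complications,-0.0040,Weak,TRUE
1452,Bladder primary malignancy,-0.0033,Direct,TRUE
1273,Congenital Anomalies,-0.0031,Direct/Weak,FALSE
1158,Lovastatin,-0.0030,Strong,FALSE
361,Treated Unstable Angina,-0.0028,Moderate,FALSE
7,Postpartum Pregnancy No Complications,-0.0027,Absent,FALSE
782,Croup vs Infective Pneumonia,-0.0027,Weak,FALSE
465,Adjustment Disorder with Anxiety,-0.0025,Weak,FALSE
362,Bacteremia,-0.0024,Weak,FALSE
343,COPD ICS LABA,-0.0023,Strong,FALSE
638,Respiratory malignancy multiple locations,-0.0023,Direct,TRUE
1962,ADHD Black Male,-0.0021,Moderate,FALSE
1109,Infective Pneumonia,-0.0018,Moderate,FALSE
864,COVID-19,-0.0018,Moderate,TRUE
1936,COPD,-0.0018,Strong,TRUE
1552,Elevated venous blood oxygen,-0.0017,Absent,FALSE
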