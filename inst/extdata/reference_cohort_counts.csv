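set,field,level,count
discovery,n_records,all,269065
discovery,sex,male,144258
discovery,sex,female,124793
discovery,race,white,202553
discovery,race,black,36814
discovery,race,unknown,17338
discovery,race,other,12360
evaluation,n_records,malignant,767
evaluation,n_records,benign,12485
evaluation,sex_malignant,male,371
evaluation,sex_malignant,female,396
evaluation,sex_benign,male,5728
evaluation,sex_benign,female,6757
evaluation,race_malignant,white,674
evaluation,race_malignant,black,63
evaluation,race_malignant,unknown,13
evaluation,race_malignant,other,17
evaluation,race_benign,white,10126
evaluation,race_benign,black,1512
evaluation,race_benign,unknown,449
evaluation,race_benign,other,398
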