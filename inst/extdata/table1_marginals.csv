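variable,category,count
head_sex,male,574
head_sex,female,251
head_age_group,<=30,191
head_age_group,31-45,343
head_age_group,46-60,182
head_age_group,>60,109
marital_status,single,55
marital_status,married,573
marital_status,separated,28
marital_status,divorced,74
marital_status,widowed,95
ownership,private,521
ownership,rent,304
occupation,self_employed,399
occupation,government,385
occupation,private_sector,41
family_size_cat,<=4,628
family_size_cat,>4,197
u5_present,yes,261
u5_present,no,564
wealth_status,poorest,163
wealth_status,poorer,160
wealth_status,middle,161
wealth_status,richer,179
wealth_status,richest,162
chronic_condition,yes,249
chronic_condition,no,576
traditional_medicine,yes,178
traditional_medicine,no,647
referral_history,yes,41
referral_history,no,654
referral_history,missing,130
che,yes,247
che,no,578
insurance,insured,194
insurance,non_insured,631
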