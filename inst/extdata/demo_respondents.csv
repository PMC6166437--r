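id,round,interview_cm,age_group,race_ethnicity,poverty,marital,religiosity,acasi_birth,acasi_loss,acasi_abortion
w1,2011-2015,1362,15-24,white_nl,0-99,never_married,lt_monthly,0,0,1
w2,2011-2015,1362,25-34,black_nl,100-299,never_married,monthly_plus,0,0,1
w3,2011-2015,1362,25-34,latina,300+,currently_married,lt_monthly,1,0,0
w4,2011-2015,1362,35-44,white_nl,0-99,previously_married,monthly_plus,1,1,0
w5,2011-2015,1362,15-24,other_nl,100-299,never_married,lt_monthly,0,0,1
w6,2011-2015,1362,35-44,latina,300+,currently_married,monthly_plus,1,0,0
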