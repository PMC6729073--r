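variable,role,direction,unit,mean,sd,min,max,hard_clip
fixed_assets,input,desirable,million yuan,2.2,3.68,0.5,16,FALSE
admin_staff,input,desirable,headcount,5.5,5.96,1,31,FALSE
medical_staff,input,desirable,headcount,5.5,8.40,1,36,FALSE
caregivers,input,desirable,headcount,24,22.32,10,115,TRUE
paramedical_staff,input,desirable,headcount,7.5,8.57,1,35,FALSE
beds,input,desirable,beds,80,96.42,24,300,TRUE
independent,output,desirable,residents,11.5,20.44,6,100,FALSE
partially_disabled,output,desirable,residents,28.5,22.56,2,85,FALSE
disabled,output,desirable,residents,33.5,53.27,4,249,FALSE
fall_rate,output,undesirable,percent,14.65,5.21,0,39.8,FALSE
complaint_unhandled,output,undesirable,percent,2.04,2.17,0,18,FALSE
accident_rate,output,undesirable,percent,0.85,0.26,0,4.71,FALSE
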