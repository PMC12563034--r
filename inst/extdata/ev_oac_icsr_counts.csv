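drug,variable,level,count
warfarin,icsr,total,41775
acenocumarol,icsr,total,8818
dabigatran,icsr,total,48341
rivaroxaban,icsr,total,101577
apixaban,icsr,total,39741
edoxaban,icsr,total,3897
warfarin,sex,F,19745
acenocumarol,sex,F,4194
dabigatran,sex,F,21284
rivaroxaban,sex,F,45438
apixaban,sex,F,18852
edoxaban,sex,F,1870
warfarin,sex,M,19789
acenocumarol,sex,M,4449
dabigatran,sex,M,23595
rivaroxaban,sex,M,45952
apixaban,sex,M,18692
edoxaban,sex,M,1936
warfarin,sex,not_specified,2241
acenocumarol,sex,not_specified,175
dabigatran,sex,not_specified,3462
rivaroxaban,sex,not_specified,10187
apixaban,sex,not_specified,2197
edoxaban,sex,not_specified,91
warfarin,age,over_85,7132
acenocumarol,age,over_85,1708
dabigatran,age,over_85,7854
rivaroxaban,age,over_85,10819
apixaban,age,over_85,7369
edoxaban,age,over_85,760
warfarin,age,65_85,21240
acenocumarol,age,65_85,5049
dabigatran,age,65_85,24389
rivaroxaban,age,65_85,45197
apixaban,age,65_85,18634
edoxaban,age,65_85,2040
warfarin,age,18_64,8452
acenocumarol,age,18_64,1580
dabigatran,age,18_64,5107
rivaroxaban,age,18_64,20184
apixaban,age,18_64,4501
edoxaban,age,18_64,415
warfarin,age,under_18,325
acenocumarol,age,under_18,46
dabigatran,age,under_18,26
rivaroxaban,age,under_18,108
apixaban,age,under_18,26
edoxaban,age,under_18,5
warfarin,age,not_specified,4626
acenocumarol,age,not_specified,435
dabigatran,age,not_specified,10965
rivaroxaban,age,not_specified,25269
apixaban,age,not_specified,9211
edoxaban,age,not_specified,677
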