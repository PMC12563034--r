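drug,variable,level,count
warfarin,adr,total,81100
acenocumarol,adr,total,17294
dabigatran,adr,total,87140
rivaroxaban,adr,total,172624
apixaban,adr,total,67104
edoxaban,adr,total,6092
warfarin,seriousness,serious,73784
acenocumarol,seriousness,serious,15357
dabigatran,seriousness,serious,81660
rivaroxaban,seriousness,serious,164925
apixaban,seriousness,serious,60991
edoxaban,seriousness,serious,4322
warfarin,seriousness,non_serious,7232
acenocumarol,seriousness,non_serious,1918
dabigatran,seriousness,non_serious,5475
rivaroxaban,seriousness,non_serious,7699
apixaban,seriousness,non_serious,6113
edoxaban,seriousness,non_serious,1770
warfarin,seriousness,not_specified,84
acenocumarol,seriousness,not_specified,19
dabigatran,seriousness,not_specified,5
rivaroxaban,seriousness,not_specified,0
apixaban,seriousness,not_specified,0
edoxaban,seriousness,not_specified,0
warfarin,outcome,fatal,6817
acenocumarol,outcome,fatal,1466
dabigatran,outcome,fatal,10774
rivaroxaban,outcome,fatal,12947
apixaban,outcome,fatal,5878
edoxaban,outcome,fatal,368
warfarin,outcome,not_recovered,5747
acenocumarol,outcome,not_recovered,969
dabigatran,outcome,not_recovered,10882
rivaroxaban,outcome,not_recovered,13382
apixaban,outcome,not_recovered,5129
edoxaban,outcome,not_recovered,841
warfarin,outcome,not_specified,2164
acenocumarol,outcome,not_specified,584
dabigatran,outcome,not_specified,12
rivaroxaban,outcome,not_specified,221
apixaban,outcome,not_specified,0
edoxaban,outcome,not_specified,0
warfarin,outcome,recovered,22603
acenocumarol,outcome,recovered,8123
dabigatran,outcome,recovered,25083
rivaroxaban,outcome,recovered,35182
apixaban,outcome,recovered,10005
edoxaban,outcome,recovered,1728
warfarin,outcome,recovered_with_sequelae,1014
acenocumarol,outcome,recovered_with_sequelae,410
dabigatran,outcome,recovered_with_sequelae,1561
rivaroxaban,outcome,recovered_with_sequelae,2085
apixaban,outcome,recovered_with_sequelae,945
edoxaban,outcome,recovered_with_sequelae,180
warfarin,outcome,recovering,12250
acenocumarol,outcome,recovering,2231
dabigatran,outcome,recovering,3118
rivaroxaban,outcome,recovering,26037
apixaban,outcome,recovering,5337
edoxaban,outcome,recovering,858
warfarin,outcome,unknown,34752
acenocumarol,outcome,unknown,4301
dabigatran,outcome,unknown,40472
rivaroxaban,outcome,unknown,89991
apixaban,outcome,unknown,42020
edoxaban,outcome,unknown,2284
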