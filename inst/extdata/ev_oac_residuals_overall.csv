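soc,warfarin,acenocumarol,dabigatran,rivaroxaban,apixaban,edoxaban
Blood,17.3,86.6,28.3,-14.8,-41.9,0.2
Card,-25.1,-35.9,54.7,-22.9,30.0,-28.2
Cong,27.7,-49.5,-37.9,40.9,-70.2,-72.7
Ear,-13.6,-36.6,-27.6,2.2,51.2,54.9
Endo,52.3,-12.0,-33.8,-7.6,5.2,-21.1
Eye,-3.1,-19.8,-31.9,5.9,34.9,1.9
Gastr,-32.3,-20.0,27.1,15.2,-29.6,-6.0
Genrl,20.5,24.1,-14.1,-11.0,17.3,-18.2
Hepato,-9.0,8.3,-1.1,-1.0,6.4,69.1
Immun,17.7,-31.4,-30.4,-7.1,37.2,80.9
Infec,-9.6,-46.2,47.0,-20.0,14.8,-8.9
Inj&P,4.4,-10.4,-18.0,-1.0,23.9,-7.3
Inv,104.0,128.0,-35.0,-28.5,-38.8,-11.9
Metab,36.3,5.1,32.1,-28.8,-10.3,-27.0
Musc,7.2,-0.1,-35.1,7.6,17.0,3.4
Neopl,-39.9,-62.1,56.2,-24.1,54.3,-10.8
Nerv,-18.6,-28.0,8.3,-4.4,26.3,43.0
Preg,255.4,149.8,-94.5,-59.9,-64.2,-68.5
Product,40.2,-39.7,-9.7,-0.3,-17.6,-79.8
Psych,24.3,8.0,-12.8,-14.4,19.8,27.2
Renal,-18.1,-8.4,11.2,14.5,-27.3,-5.2
Repro,-36.2,-56.7,-58.2,67.6,-38.1,-21.4
Resp,7.3,-17.4,-16.3,11.2,-12.4,6.7
Skin,0.1,11.9,-28.3,-3.1,30.4,122.6
Surg,-32.3,-45.6,-41.7,-17.8,156.1,-56.2
Vasc,-8.4,-19.9,-12.0,13.8,-1.1,-37.1
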