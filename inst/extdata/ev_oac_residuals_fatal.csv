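soc,warfarin,acenocumarol,dabigatran,rivaroxaban,apixaban,edoxaban
Blood,6.4,77.9,44.8,-24.9,-52.3,8.2
Card,-21.0,-25.7,34.2,-10.0,-8.8,-36.3
Cong,209.7,53.5,-52.4,-28.6,-82.7,-100.0
Endo,106.2,127.2,-85.9,29.1,-48.7,-100.0
Gastr,-32.4,-15.0,53.9,-2.7,-50.5,-30.8
Genrl,-19.2,-43.4,-13.7,-16.7,95.3,-38.3
Hepato,-14.1,62.3,-3.1,2.7,-10.7,191.1
Immun,167.3,89.3,-6.0,-60.9,-57.2,-100.0
Infec,-27.3,-34.7,39.2,-7.4,-18.1,21.2
Inj&P,69.1,49.1,-25.5,-4.7,-31.6,-3.1
Metab,43.2,70.0,26.6,-33.9,-32.3,-100.0
Musc,74.8,309.1,-64.1,4.4,-40.2,-100.0
Neopl,-29.1,-75.2,7.1,-14.6,66.8,27.4
Nerv,19.4,20.8,-36.9,19.3,-4.1,40.5
Preg,386.1,72.1,-89.3,-91.1,-100.0,208.8
Psych,292.4,25.7,-82.6,-45.8,-76.6,-100.0
Renal,-31.1,37.2,48.1,-6.4,-45.2,-31.3
Repro,-9.1,35.2,45.5,-6.9,-59.3,-100.0
Resp,-26.1,-22.6,2.1,21.7,-20.9,63.2
Skin,135.1,97.0,-24.6,-40.6,-44.4,76.7
Vasc,-21.6,12.0,27.9,1.1,-30.3,-20.9
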