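"variable","comparison","statistic","df","p","estimate","ci_lo","ci_hi","significant","degenerate","error"
"ESV","healthy vs unhealthy",-1.48444705118956,40,0.145528693281576,-10.277383697166,-22.6084693723139,4.46450986943256,FALSE,FALSE,NA
"ESV","male vs female",1.54332111607732,40,0.130628230573878,10.5531350097429,0.417647509666551,27.3180047464439,FALSE,FALSE,NA
"EDV","healthy vs unhealthy",-0.866954065420107,40,0.391138254528621,-9.46218322542254,-25.915843239156,9.36559008810826,FALSE,FALSE,NA
"EDV","male vs female",0.6201626203063,40,0.538668035422677,6.72957923685379,-18.0263623065321,23.5121817838452,FALSE,FALSE,NA
"LVEF","healthy vs unhealthy",1.47330878609939,40,0.148494187048043,2.71875545413944,-0.79840538892658,6.03716847967786,FALSE,FALSE,NA
"LVEF","male vs female",-2.96039467413641,40,0.00514524384492289,-5.0281042129636,-8.98063930256133,-0.968713356064218,TRUE,FALSE,NA
"ESVi","healthy vs unhealthy",-0.726438566353842,40,0.471799782486359,-2.80049240954343,-9.78313463423684,3.26603547088255,FALSE,FALSE,NA
"ESVi","male vs female",1.18027714365335,40,0.244861457884745,4.45609453377543,-4.29274475744196,11.7786338066136,FALSE,FALSE,NA
"BSA","healthy vs unhealthy",-1.2316600759604,40,0.225268081810739,-0.0786405943975093,-0.196454905332706,0.0265142582295359,FALSE,FALSE,NA
"BSA","male vs female",1.34454212064079,40,0.186348578825545,0.0846714899212431,-0.0212900048075376,0.19005695346485,FALSE,FALSE,NA
"ACS","healthy vs unhealthy",0.126967881118472,40,0.899601945004795,0.459351657163772,-5.19752412140755,6.40561722109349,FALSE,FALSE,NA
"ACS","male vs female",2.84961196348571,40,0.00688559851782776,9.30492982170169,4.93622082744698,14.8524863889786,TRUE,FALSE,NA
"MCS","healthy vs unhealthy",-2.55854065319491,40,0.0144016431667382,-5.48123076133581,-9.25900159713047,-1.15513301866673,TRUE,FALSE,NA
"MCS","male vs female",2.3872239207263,40,0.0217922005374477,5.10846841052906,0.95609674520419,8.3692852674539,TRUE,FALSE,NA
"BCS","healthy vs unhealthy",0.0617535831701437,40,0.951066608638723,0.100480006337456,-3.82214905269539,3.10363595830345,FALSE,FALSE,NA
"BCS","male vs female",0.756069805900904,40,0.454037229271877,1.20904195637361,-1.81094295992095,4.2433930172319,FALSE,FALSE,NA
"GCS","healthy vs unhealthy",-1.03323668883404,40,0.307699981297522,-1.48512588446821,-3.84922177759761,1.12869531284922,FALSE,FALSE,NA
"GCS","male vs female",4.19119203977639,40,0.000148841573909884,5.03604688385071,2.99564329366033,7.86581799411998,TRUE,FALSE,NA
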