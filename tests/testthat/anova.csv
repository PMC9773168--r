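"variable","F","df1","df2","p","gated_in","error"
"ESV",2.57760054287601,11,30,0.0195148861615106,TRUE,NA
"EDV",1.29798668063393,11,30,0.273024843184521,FALSE,NA
"LVEF",3.98499090232554,11,30,0.00125496536606477,TRUE,NA
"ESVi",1.76554333744299,11,30,0.10618344890249,FALSE,NA
"BSA",1.6613031484976,11,30,0.131764581052668,FALSE,NA
"ACS",2.81085315330158,11,30,0.0121129553454287,TRUE,NA
"MCS",3.44704341315045,11,30,0.00344271413503847,TRUE,NA
"BCS",2.28472607533617,11,30,0.0358366371292499,TRUE,NA
"GCS",4.55757922338563,11,30,0.000453337437126715,TRUE,NA
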