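"contrast","variable","p"
"All FU vs All MU","GCS",0.000108869339032683
"All FU vs All MU","MCS",0.000943962131258868
"All MH vs All MU","MCS",0.000714694252350637
"MH55-64 vs MU55-64","LVEF",0.000315677304871526
"MH55-64 vs MU55-64","MCS",0.000435515787947542
"MU55-64 vs MU65-74","BCS",0.000429307152511421
"MU55-64 vs MU65-74","ESV",0.00228499130522992
"MU55-64 vs MU65-74","LVEF",0.00126176253713379
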