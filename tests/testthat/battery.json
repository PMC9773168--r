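{"threshold":0.003,"alpha":0.05,"seed":438540986,"boot_reps":50,"significant":[{"contrast":"All FU vs All MU","variable":"GCS","p":0.000108869339032683},{"contrast":"All FU vs All MU","variable":"MCS","p":0.000943962131258868},{"contrast":"All MH vs All MU","variable":"MCS","p":0.000714694252350637},{"contrast":"MH55-64 vs MU55-64","variable":"LVEF","p":0.000315677304871526},{"contrast":"MH55-64 vs MU55-64","variable":"MCS","p":0.000435515787947542},{"contrast":"MU55-64 vs MU65-74","variable":"BCS","p":0.000429307152511421},{"contrast":"MU55-64 vs MU65-74","variable":"ESV","p":0.00228499130522992},{"contrast":"MU55-64 vs MU65-74","variable":"LVEF","p":0.00126176253713379}]}
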