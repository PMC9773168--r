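{"timestamp":"2026-09-26T21:50:21","stage":"pipeline","master_seed":3,"subjects_generated":48,"subjects_selected":42,"outliers_removed":0,"contours_processed":3990,"contours_corrected":0,"correction_rate_pct":0}
{"timestamp":"2026-09-26T21:50:22","stage":"pipeline","master_seed":3,"subjects_generated":48,"subjects_selected":42,"outliers_removed":0,"contours_processed":3990,"contours_corrected":0,"correction_rate_pct":0}
{"timestamp":"2026-09-26T21:54:43","stage":"pipeline","master_seed":3,"subjects_generated":48,"subjects_selected":42,"outliers_removed":0,"contours_processed":3990,"contours_corrected":0,"correction_rate_pct":0}
{"timestamp":"2026-09-26T21:54:44","stage":"pipeline","master_seed":3,"subjects_generated":48,"subjects_selected":42,"outliers_removed":0,"contours_processed":3990,"contours_corrected":0,"correction_rate_pct":0}
{"timestamp":"2026-09-26T21:55:30","stage":"pipeline","master_seed":3,"subjects_generated":48,"subjects_selected":42,"outliers_removed":0,"contours_processed":3990,"contours_corrected":0,"correction_rate_pct":0}
{"timestamp":"2026-09-26T21:55:32","stage":"pipeline","master_seed":3,"subjects_generated":48,"subjects_selected":42,"outliers_removed":0,"contours_processed":3990,"contours_corrected":0,"correction_rate_pct":0}
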