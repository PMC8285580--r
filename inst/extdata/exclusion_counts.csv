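# Per-criterion exclusive exclusion counts of the emulated longitudinal
# infant cohort, by assessment age. "enrolled" is the number of datasets
# available at each age before exclusions.
age_months,enrolled,criterion,n
5,104,withdrawn,3
5,104,missed_visit,1
5,104,no_nirs,7
5,104,fussy,6
5,104,missing_photos,5
5,104,missing_video,8
5,104,missing_markers,1
5,104,technical,1
5,104,poor_placement,5
5,104,pruning_below_threshold,5
5,104,insufficient_trials,3
5,104,missing_circumference,6
8,97,withdrawn,8
8,97,missed_visit,2
8,97,no_nirs,9
8,97,fussy,5
8,97,missing_photos,4
8,97,missing_video,5
8,97,missing_markers,0
8,97,technical,1
8,97,poor_placement,12
8,97,pruning_below_threshold,1
8,97,insufficient_trials,3
8,97,missing_circumference,7
12,97,withdrawn,9
12,97,missed_visit,2
12,97,no_nirs,11
12,97,fussy,9
12,97,missing_photos,1
12,97,missing_video,3
12,97,missing_markers,0
12,97,technical,2
12,97,poor_placement,6
12,97,pruning_below_threshold,1
12,97,insufficient_trials,4
12,97,missing_circumference,4
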