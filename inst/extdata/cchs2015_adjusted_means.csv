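outcome,stratum,wg_group,lsmean,se,unit
folic_acid,child,no_wg,147,6,ug
folic_acid,child,low_wg,151,9,ug
folic_acid,child,mid_wg,124,7,ug
folic_acid,child,high_wg,116,7,ug
folic_acid,adult,no_wg,123,3,ug
folic_acid,adult,low_wg,109,4,ug
folic_acid,adult,mid_wg,94,4,ug
folic_acid,adult,high_wg,79,4,ug
discretionary,child,no_wg,191,18,g
discretionary,child,low_wg,164,19,g
discretionary,child,mid_wg,175,18,g
discretionary,child,high_wg,152,14,g
discretionary,adult,no_wg,315,14,g
discretionary,adult,low_wg,251,16,g
discretionary,adult,mid_wg,228,17,g
discretionary,adult,high_wg,163,17,g
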