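table,column,positive,negative,no_significance,ci_lo,ci_hi
table1_fss,baseline_maxQ,10,12,10,-0.15,0.037
table1_fss,baseline_minQ,9,13,10,-.163,0.024
table1_fss,followup_maxQ,19,9,4,-0.015,0.155
table1_fss,followup_minQ,20,7,5,0.01,0.172
table2_pws,baseline_maxQ,18,5,9,0.039,0.184
table2_pws,baseline_minQ,18,5,9,0.041,0.185
table2_pws,followup_maxQ,2,26,4,-0.273,-0.142
table2_pws,followup_minQ,2,26,4,-0.273,-0.143
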