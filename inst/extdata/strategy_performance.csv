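line,label,retrieved,crts_retrieved,n_relevant,corpus_total
5,rct_pt,1697,152,162,25707
6,cluster_adj_randomized,87,59,162,25707
7,community_terms,96,16,162,25707
8,group_randomized,34,9,162,25707
9,cluster_terms,208,78,162,25707
10,intervention_tw,2636,139,162,25707
11,cluster_analysis_mesh,150,30,162,25707
12,health_promotion_mesh,796,38,162,25707
13,program_evaluation_mesh,560,36,162,25707
14,health_education_mesh,428,32,162,25707
15,broad_terms,3658,149,162,25707
16,combined_terms,3680,155,162,25707
17,highest_sensitivity,4583,161,162,25707
18,highest_precision,794,146,162,25707
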