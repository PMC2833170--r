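review,period_start,period_end,n_trials,retrieved_simple,retrieved_highest_sensitivity,retrieved_highest_precision
donner_nontherapeutic,1979,1989,16,16,16,8
simpson_primary_care,1990,1993,21,15,20,15
eldridge_primary_care_a,1997,2000,145,140,142,121
isaakidis_africa,1996,2001,51,45,48,33
puffer_general,1997,2002,36,36,36,33
varnell_group_randomized,1998,2002,60,54,59,51
eldridge_primary_care_b,2004,2005,34,34,34,32
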