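domain,n_structured,n_confirmed,n_nlp_positive,n_overlap_structured,cohort_n
social_connections,16,197,313,15,4283
employment,4,197,358,3,4283
housing,26,111,448,23,4283
food,39,102,157,39,4283
education,4,35,71,4,4283
finance,4,113,211,4,4283
stress,14,222,510,11,4283
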