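whale_id,body_length_m,collection_month,collection_year,baleen_length_cm,length_age_yr,aar_age_yr,age_override_yr,gumline_cut
whale1,10.51,9,2008,181,10,14,NA,FALSE
whale2,13.43,8,2008,235,29,18,NA,FALSE
whale3,12.75,7,1998,266,22,21,NA,FALSE
whale4,12.80,8,2010,230,23,NA,NA,FALSE
whale5,11.65,8,2000,270,15,24,NA,TRUE
whale6,14.10,4,2009,204,41,44,NA,TRUE
whale7,14.33,8,2011,298,48,NA,NA,FALSE
whale8,14.88,8,2008,319,78,115,NA,FALSE
whale9,15.77,9,2009,330,153,NA,NA,FALSE
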