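whale_id,est_age_yr,n_t_peaks,t_period_cm,n_period_cm,phase_offset_months,mean_t_peak_ng_g,sd_t_peak_ng_g,baseline_t_ng_g,sd_baseline_t_ng_g,mean_ratio,sd_ratio,max_t_ng_g,min_t_ng_g,mean_t_ng_g,median_t_ng_g
whale1,14,5,18.35,15.50,0.00,3.06,1.03,0.90,0.29,4.04,2.95,4.87,0.53,1.64,1.52
whale2,18,11,19.23,20.80,2.50,2.78,0.66,0.73,0.25,3.71,1.37,3.73,0.28,1.65,1.49
whale3,21,12,21.51,20.60,3.35,11.77,2.00,1.22,0.28,9.70,3.54,15.67,0.80,5.19,4.70
whale4,23,12,16.95,17.50,2.83,7.19,1.50,1.22,0.47,6.29,1.74,9.89,0.62,3.80,3.14
whale5,24,15,17.54,17.90,2.74,3.99,0.72,0.81,0.19,5.00,1.35,5.53,0.46,2.23,1.91
whale6,44,13,16.53,17.20,2.90,8.10,1.59,1.36,0.51,6.85,3.40,11.05,0.51,4.39,4.05
whale7,48,16,16.13,17.10,2.98,4.26,1.22,0.72,0.36,7.79,5.82,5.65,0.18,2.21,1.76
whale8,115,20,14.49,14.60,3.31,9.10,3.05,2.24,0.32,4.12,1.47,14.70,1.79,5.37,4.65
whale9,153,22,14.49,14.90,1.66,10.96,4.53,2.83,0.84,4.49,2.77,21.56,1.72,6.61,5.82
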