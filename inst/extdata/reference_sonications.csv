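milk_fraction,power_W,peak_exp_C,peak_exp_sd_C,peak_sim_C,fwhm_tr_exp_mm,fwhm_tr_exp_sd_mm,fwhm_tr_sim_mm,fwhm_lg_exp_mm,fwhm_lg_exp_sd_mm,fwhm_lg_sim_mm,noise_C,snr
10,6.3,2.36,0.21,2.66,2.73,0.08,2.76,16.74,0.81,19.00,0.240,9.84
30,6.3,4.41,0.42,4.58,2.88,0.09,2.76,18.14,0.33,19.00,0.156,24.69
50,6.3,6.17,0.26,6.49,2.77,0.10,2.78,16.92,0.46,19.08,0.160,32.39
70,6.3,8.04,0.16,8.15,2.78,0.05,2.74,17.23,0.50,18.92,0.201,40.13
10,7.9,2.87,0.12,3.33,2.77,0.19,2.76,17.52,0.12,19.00,0.177,13.01
30,7.9,5.57,0.41,5.75,2.83,0.12,2.76,16.84,0.79,19.00,0.186,27.31
50,7.9,7.64,0.57,8.14,2.79,0.12,2.78,17.88,0.94,19.08,0.172,36.15
70,7.9,9.64,0.34,10.23,2.82,0.06,2.74,17.39,0.43,18.92,0.151,54.32
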