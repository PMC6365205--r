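milk_fraction,alpha0_np_per_cm,alpha0_rel_sd,sos_m_s,sos_rel_sd,rho_kg_m3,rho_rel_sd,vhc_kj_m3C,vhc_rel_sd,kappa_w_mC,kappa_rel_sd
10,0.015,0.16,1540.0,0.001,1022,0.008,3404,0.10,0.554,0.10
30,0.027,0.16,1552.0,0.001,1050,0.008,3361,0.10,0.545,0.10
50,0.042,0.16,1560.3,0.001,1040,0.008,3371,0.10,0.565,0.10
70,0.053,0.16,1571.7,0.001,1050,0.008,3381,0.10,0.525,0.10
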