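organelle,parameter,symbol,unit,mean_viable,sd_viable,n_viable,mean_apoptotic,sd_apoptotic,n_apoptotic,p_printed,consistent
cell,Grid perimeter,GP_c,um,7047,2642,101,9140,4719,105,1.17e-04,TRUE
cell,Surface area,S_c,um2,1663,448.4,101,1637,561.4,105,7.14e-01,TRUE
cell,Volume,V_c,um3,3681,1560,101,3409,1730,105,2.39e-01,TRUE
cell,Surface-to-volume ratio,SVr_c,um-1,0.475,0.0658,101,0.521,0.121,105,8.48e-04,TRUE
cell,Inflection point number,N_si,-,7.277,6.854,101,16.57,16.14,105,2.55e-07,TRUE
cell,Surface irregularity index,SIi_c,um-1/2,116.6,27.94,101,156.7,59.01,105,3.53e-09,TRUE
cell,Equivalent radius,ER_c,um,9.420,1.217,101,9.102,1.478,105,9.41e-02,TRUE
cell,Volume sphericity index,VSi_c,-,0.6828,0.0356,101,0.6592,0.0670,105,1.83e-03,TRUE
cell,Mean mem-to-cen distance,R_c_mean,um,9.447,1.252,101,9.257,1.560,105,3.36e-01,TRUE
cell,std of R_c,R_c_std,um,0.5275,0.2723,101,0.7933,0.3876,105,4.35e-08,TRUE
nucleus,Grid perimeter,GP_n,um,3520,1504,101,4566,2739,105,8.05e-04,TRUE
nucleus,Surface area,S_n,um2,827.8,271.8,101,820.8,430.5,105,8.89e-01,TRUE
nucleus,Volume,V_n,um3,1228,580.5,101,1122,755.1,105,2.60e-01,TRUE
nucleus,Surface-to-volume ratio,SVr_n,um-1,0.713,0.103,101,0.798,0.178,105,3.58e-05,TRUE
nucleus,Surface irregularity index,SIi_n,um-1/2,100.8,29.39,101,136.4,53.07,105,1.38e-08,TRUE
nucleus,Equivalent radius,ER_n,um,6.507,0.9365,101,6.228,1.151,105,5.83e-02,TRUE
nucleus,Volume sphericity index,VSi_n,-,0.6612,0.04020,101,0.6299,0.0672,105,7.13e-05,TRUE
nucleus,Mean mem-to-cen distance,R_n_mean,um,6.607,1.023,101,6.558,1.205,105,7.54e-01,TRUE
nucleus,std of R_n,R_n_std,um,0.9321,0.3569,101,1.157,0.5314,105,4.40e-04,TRUE
nucleus,Nucleus-to-cell centroid distance,CD_nc,um,1.430,0.833,101,1.718,1.233,105,5.05e-02,TRUE
nucleus,Nucleus-to-cell volume ratio,Vr_nc,-,0.3396,0.0939,101,0.3419,0.1316,105,8.88e-01,TRUE
nucleus,Syto-61 fluorescence,I_n_mean,-,153000,70800,101,93100,64600,105,1.43e-09,TRUE
mitochondria,Grid perimeter,GP_m,um,313,300,101,3487,3213,105,4.08e-01,FALSE
mitochondria,Surface area,S_m,um2,773,493,101,646,468,105,5.97e-02,TRUE
mitochondria,Volume,V_m,um3,251,195,101,191,163,105,1.68e-02,TRUE
mitochondria,Surface-to-volume ratio,SVr_m,um-1,3.5,0.84,101,4.1,1.5,105,3.82e-04,TRUE
mitochondria,Surface irregularity index,SIi_m,um-1/2,189,98.2,101,238,145,105,4.26e-03,TRUE
mitochondria,Equivalent radius,ER_m,um,0.919,0.236,101,0.817,0.250,105,2.82e-03,TRUE
mitochondria,Mitochondrion-to-cell volume ratio,Vr_mc,-,0.067,0.038,101,0.054,0.032,105,5.99e-03,FALSE
mitochondria,Mito-Tracker fluorescence,I_m_mean,-,220000,54400,101,212000,77400,105,4.04e-01,TRUE
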