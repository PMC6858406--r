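group,term,beta,se,ci_low,ci_high,p,r2,adj_r2,see_abs,see_pct,cv_residual_abs,cv_residual_pct,dw,dev_n,cv_n,dev_mv_mean,dev_mv_sd,cv_mv_mean
hip_extensors,constant,1087.037,410.022,193.676,1980.398,0.021,0.690,0.665,283.01,8.92,-347.32,11.28,1.67,14,3,3171.9,488.7,3078.8
hip_extensors,mass_kg.thigh_length_m,64.946,12.554,37.594,92.298,0.001,0.690,0.665,283.01,8.92,-347.32,11.28,1.67,14,3,3171.9,488.7,3078.8
knee_extensors,constant,996.168,257.349,429.747,1562.588,0.003,0.707,0.681,121.10,5.24,20.11,0.95,2.32,13,3,2311.6,214.3,2110.32
knee_extensors,mt_ant50_cm.mass_kg,4.664,0.905,2.673,6.655,0.001,0.707,0.681,121.10,5.24,20.11,0.95,2.32,13,3,2311.6,214.3,2110.32
knee_flexors,constant,1199.444,161.753,843.428,1555.461,0.001,0.357,0.298,125.37,7.89,-42.72,-2.66,2.18,13,3,1589.5,149.6,1607.2
knee_flexors,mt_bfsh75_cm.thigh_length_m,318.147,128.860,34.528,601.766,0.031,0.357,0.298,125.37,7.89,-42.72,-2.66,2.18,13,3,1589.5,149.6,1607.2
ankle_plantarflexors,constant,878.606,140.417,572.662,1184.549,0.001,0.387,0.336,134.91,10.78,92.44,6.37,1.44,14,4,1252.0,165.5,1451.5
ankle_plantarflexors,csa_lg25_cm2.mass_kg,0.553,0.201,0.115,0.991,0.018,0.387,0.336,134.91,10.78,92.44,6.37,1.44,14,4,1252.0,165.5,1451.5
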