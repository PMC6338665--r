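temperature_C,n,mass_min_g,mass_max_g,d13C_oto,d13C_oto_sd,d18O_oto,d18O_oto_sd,d13C_DIC_1,d13C_DIC_2,d13C_diet,d13C_diet_sd,m_oto,m_oto_sd,o2_mgkg_h,o2_sd
4,11,118,298,-2.23,0.23,3.59,0.21,-0.15,-0.22,-19.96,0.30,0.10,0.012,70,6.5
7,15,111,410,-2.87,0.44,2.74,0.26,-0.13,-0.23,-20.13,0.68,0.14,0.024,93,10
10,19,128,678,-3.25,0.35,2.27,0.29,-0.27,-0.32,-20.80,0.82,0.14,0.017,105,16
14,18,94,530,-4.02,0.33,1.50,0.30,-0.21,-0.31,-21.38,0.63,0.18,0.015,145,28
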