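group,molecule,parent,site,volume,vol_increase_pct,logp,logp_increase_pct,coupling_value
CH3,DMP-1-CH3-2-CH2NO2,DMP,1+2,75.0,3650.00,1.30,-15.58,828.85
CH3,DMP-1-CH3-2-NO2,DMP,1+2,61.0,2950.00,0.84,-45.45,655.14
CH3,DAP-1-NO2-2-CH3,DAP,1+2,61.0,2950.00,2.77,-9.48,671.29
CH3,DAP-2-CH=CH2-1-CH3,DAP,1+2,42.0,2000.00,3.75,22.55,468.12
CH2CH3,DAP-1-NO2-2-CH2CH3,DAP,1+2,75.1,3655.00,3.18,3.92,838.76
CH2C6H5,DAP-1-NO2-2-CH2C6H5,DAP,1+2,137.1,6755.00,4.37,42.81,1566.12
NO2,DMP-1-NO2,DMP,1,46.0,4500.00,0.56,-63.64,1001.93
NO2,DMP-1-CH3-2-NO2,DMP,1+2,61.0,2950.00,0.84,-45.45,655.14
NO2,DAP-2-NO2,DAP,2,46.0,4500.00,2.93,-4.25,1028.59
NO2,DAP-1-NO2-2-CH2C6H5,DAP,1+2,137.1,6755.00,4.37,42.81,1566.12
NO2,DAP-1-NO2-2-CH2CH2CH3,DAP,1+2,89.1,4355.00,3.60,17.65,1005.22
NO2,DAP-1-NO2-2-CH2CH3,DAP,1+2,75.1,3655.00,3.18,3.92,838.76
NO2,DAP-1-NO2-2-CH2NO2,DAP,1+2,106.0,5200.00,2.38,-22.22,1180.82
NO2,DAP-1-NO2-2-CH3,DAP,1+2,61.0,2950.00,2.77,-9.48,671.29
NO2,DAP-1-NO2-2-CH=CH2,DAP,1+2,73.0,3550.00,2.91,-4.90,810.75
NO2,DAP-1-NO2-2-NO2,DAP,1+2,92.0,4500.00,2.28,-25.49,1019.05
NO2,DAP-1-NO2-2-OCH3,DAP,1+2,77.0,3750.00,1.96,-35.95,842.61
NO2,DAP-1-NO2-2-SH,DAP,1+2,79.1,3855.00,2.43,-20.59,873.55
NO2,DAP-2-CH=CH2-1-NO2,DAP,1+2,73.0,3550.00,2.91,-4.90,810.75
CH2NO2,DMP-1-CH2NO2,DMP,1,60.0,5900.00,1.01,-34.42,1335.65
CH2NO2,DMP-1-CH3-2-CH2NO2,DMP,1+2,75.0,3650.00,1.30,-15.58,828.85
CH2NO2,DAP-1-CH2NO2,DAP,1,60.0,5900.00,2.85,-6.86,1348.02
CH2NO2,DAP-2-CH2NO2,DAP,2,60.0,5900.00,3.04,-0.65,1350.81
CH2NO2,DAP-1-NO2-2-CH2NO2,DAP,1+2,106.0,5200.00,2.38,-22.22,1180.82
CH2NO2,DAP-2-CH=CH2-1-CH2NO2,DAP,1+2,87.0,4250.00,3.37,10.13,977.80
SH,DAP-1-SH,DAP,1,33.1,3210.00,2.55,-16.67,727.61
SH,DAP-2-SH,DAP,2,33.1,3210.00,3.09,0.98,735.53
SH,DAP-1-NO2-2-SH,DAP,1+2,79.1,3855.00,2.43,-20.59,873.55
SH,DAP-2-CH=CH2-1-SH,DAP,1+2,60.1,2905.00,3.07,0.33,665.39
OCH3,DAP-1-NO2-2-OCH3,DAP,1+2,77.0,3750.00,1.96,-35.95,842.61
OCH3,DAP-2-CH=CH2-1-OCH3,DAP,1+2,58.0,2800.00,2.60,-15.03,634.45
CH=CH2,DAP-1-NO2-2-CH=CH2,DAP,1+2,73.0,3550.00,2.91,-4.90,810.75
CH=CH2,DAP-2-CH=CH2-1-CH2NO2,DAP,1+2,87.0,4250.00,3.37,10.13,977.80
CH=CH2,DAP-2-CH=CH2-1-CH3,DAP,1+2,42.0,2000.00,3.75,22.55,468.12
CH=CH2,DAP-2-CH=CH2-1-NO2,DAP,1+2,73.0,3550.00,2.91,-4.90,810.75
CH=CH2,DAP-2-CH=CH2-1-OCH3,DAP,1+2,58.0,2800.00,2.60,-15.03,634.45
CH=CH2,DAP-2-CH=CH2-1-SH,DAP,1+2,60.1,2905.00,3.07,0.33,665.39
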