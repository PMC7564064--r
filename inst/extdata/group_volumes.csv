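group,volume
H,1.0
CH3,15.0
CH=CH2,27.0
CH2CH3,29.1
OCH3,31.0
SH,33.1
CH2CH2CH3,43.1
NO2,46.0
CH2NO2,60.0
CH2C6H5,91.1
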