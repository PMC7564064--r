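molecule,logp,site_volume_baseline,combined_volume_baseline
DMP,1.54,1.0,2.0
DAP,3.06,1.0,2.0
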