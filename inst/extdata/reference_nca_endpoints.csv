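analyte,dose_level,cmax,auc_last,c_avg
plasma_parent,0.1,22.6,16.2,0.675
plasma_parent,0.3,44.7,54.8,2.283
plasma_parent,1.0,201.3,229.6,9.566
pbmc_triphosphate,0.1,0.057,0.609,0.025
pbmc_triphosphate,0.3,0.125,1.746,0.073
pbmc_triphosphate,1.0,0.593,6.086,0.254
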