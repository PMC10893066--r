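group,animal,zero_order,first_order,higuchi,ritger_peppas
isl_only,1,0.9680,-6.6068,0.7054,NA
isl_only,2,0.8933,-4.0118,0.5972,0.9909
isl_only,3,0.9409,-4.5061,0.6568,0.9944
isl_only,4,0.9776,-3.0757,0.7388,0.9908
isl_only,5,0.9888,-4.3850,0.7672,0.9942
isl_plus,6,0.9805,-6.5246,0.8384,0.9855
isl_plus,7,0.8667,-4.2326,0.5859,0.9844
isl_plus,8,0.8971,-4.7319,0.6481,0.9399
isl_plus,9,0.9825,-4.8870,0.7619,0.9878
isl_plus,10,0.9615,-4.6075,0.6997,0.9978
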