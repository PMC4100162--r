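complex	dE_ele	dE_vdW	dG_PB	dG_np
R-AMC	-172.62	-33.5	170.65	-5.44
D-AMC	-106.88	-31.4	129.89	-5.46
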