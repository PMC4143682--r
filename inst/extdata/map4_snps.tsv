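vid	maf
3-47894286	0.0085
3-47913455	0.0085
3-47933630	0.0128
3-47933903	0.0128
3-47950674	0.0043
3-47950908	0
3-47951458	0
3-47951670	0.0043
3-47952843	0.0214
3-47953352	0.0043
3-47953405	0.3718
3-47953733	0.3162
3-47953813	0.0043
3-47953876	0.0043
3-47956424	0.3590
3-47957741	0
3-47957996	0.0214
3-47958037	0.3120
3-48040283	0.0256
3-48040284	0.0214
3-48123540	0.3162
3-48138082	0.3162
3-48140634	0.3205
3-48413179	0.4017
3-48508585	0.2521
3-48519821	0.2564
3-48520289	0.2222
3-48531227	0.1795
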