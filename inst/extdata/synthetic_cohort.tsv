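id	sex	litter	SNP001	SNP002	SNP003	SNP004	SNP005	SNP006
F0_001	M	ind0001	1	1	2	1	2	2
F0_002	M	ind0002	0	2	2	1	1	1
F0_003	M	ind0003	1	2	0	1	1	2
F0_004	M	ind0004	1	0	1	1	1	1
F0_005	F	ind0005	1	1	1	0	0	1
F0_006	F	ind0006	1	1	2	2	2	1
F0_007	F	ind0007	2	2	1	0	1	1
F0_008	F	ind0008	0	0	2	0	2	1
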