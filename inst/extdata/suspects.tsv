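name	class	formula	polarity	rt_min	precursor_mz	experimental_mz	reported_ppm	mz_convention	product_mz	collision_energy_v	me_factor
acesulfame-K	artificial sweetener	C4H5NO4S	negative	5.5	161.9861	161.9861	0.00	hydrogen	82.03	16.5	0.28
aspartame	artificial sweetener	C14H18N2O5	negative	19.7	293.1137	293.1136	0.34	hydrogen	261.08	21.7	0.12
cyclamate	artificial sweetener	C6H13NO3S	negative	8.7	178.0538	178.0535	1.68	hydrogen	79.95	17.1	0.20
saccharin	artificial sweetener	C7H5NO3S	negative	7.5	181.9912	181.9910	1.10	hydrogen	105.96	17.3	0.8073
sucralose	artificial sweetener	C12H19Cl3O8	negative	11.8	395.0067	395.0074	-1.77	hydrogen	359.00	15.0	0.25
caffeine	pharmaceutical	C8H10N4O2	positive	11.2	195.0876	195.0875	0.54	proton	138.06	17.8	1.32
carbamazepine	pharmaceutical	C15H12N2O	positive	16.9	237.1022	237.1023	-0.42	proton	194.10	19.5	0.65
ibuprofen	pharmaceutical	C13H18O2	negative	20.9	205.1229	205.1227	0.98	hydrogen	160.88	18.2	0.55
paracetamol	pharmaceutical	C8H9NO2	positive	8.7	152.0706	152.0704	1.32	proton	110.06	16.1	1.1247
butyl paraben	paraben	C11H14O3	negative	19.3	193.0870	193.0868	1.03	proton	92.03	17.7	0.10
ethyl paraben	paraben	C9H10O3	negative	16.5	165.0557	165.0560	-1.82	proton	92.03	16.5	0.15
methyl paraben	paraben	C8H8O3	negative	14.8	151.0401	151.0404	-1.99	proton	92.03	16.0	0.18
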