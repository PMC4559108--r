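name	mz_ref	ion_mode	rt_min_ref	msi_level
creatine	132.0768	positive	1.10	ID
creatinine	114.0662	positive	1.25	ID
trimethylamine oxide	76.0757	positive	0.90	ID
valine	118.0863	positive	1.60	ID
glutamine	147.0764	positive	1.05	ID
methylguanosine	298.1146	positive	4.20	Putative A
methylinosine	283.1037	positive	3.80	Putative A
dimethylguanosine	312.1303	positive	4.90	Putative A
N-acetylcytidine	286.1034	positive	3.20	ID
aniline isomer	94.0651	positive	5.60	Putative C
urobilinogen	593.3334	positive	8.70	Putative A
urobilin	591.3177	positive	9.30	Putative A
lactic acid	89.0244	negative	1.40	ID
citric acid	191.0197	negative	1.80	ID
hippuric acid	178.0510	negative	6.20	ID
ascorbic acid	175.0248	negative	1.30	ID
orotic acid	155.0098	negative	1.55	ID
cholic acid	407.2803	negative	11.40	ID
2-hydroxy-3-methylbutyric acid	117.0557	negative	4.60	Putative A
3-methyl-2-oxovaleric acid	129.0557	negative	5.20	Putative A
threonolactone	117.0193	negative	1.70	Putative C
hydroxyretinoic acid glucuronide	491.2287	negative	12.10	Putative C
ketoretinoic acid glucuronide	489.2130	negative	12.60	Putative C
urobilinogen	591.3188	negative	8.75	Putative A
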