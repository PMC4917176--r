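level	journal	articles	mentions
mention	BMC Bioinformatics	6033	203882
mention	BMC Genomics	5758	158331
mention	Bioinformatics	1338	32815
mention	Nucleic Acids Res	11121	269875
mention	BMC Syst Biol	1067	24461
mention	BMC Plant Biol	1381	25787
mention	Genome Biol	3002	55694
mention	BMC Evol Biol	2477	42201
mention	PLoS Comput Biol	3095	47614
mention	Zookeys	1419	19729
document	BMC Genomics	5758	50302
document	BMC Bioinformatics	6033	44528
document	BMC Evol Biol	2477	16658
document	BMC Plant Biol	1381	8750
document	Bioinformatics	1338	8103
document	Nucleic Acids Res	11121	64249
document	BMC Syst Biol	1067	5837
document	Bioinformation	1109	5670
document	Genome Biol	3002	14973
document	PLoS Genet	4029	18366
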