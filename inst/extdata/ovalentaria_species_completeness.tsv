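family	species	pct_missing	n_loci	pct_presence	ungapped_length	ungapped_locus_length
Atherinopsidae	Menidia_menidia	14.4	98	91.6	70824	723
Pseudomugilidae	Pseudomugil_signifer	10.9	104	97.2	73735	709
Aplocheilidae	Aplocheilus_lineatus	8.4	105	98.1	75857	722
Fundulidae	Lucania_goodei	21.4	95	88.8	65080	685
Belonidae	Strongylura_marina	9.0	106	99.1	75367	711
Chaenopsidae	Acanthemblemaria_spinosa	13.0	99	92.5	72021	727
Tripterygiidae	Enneanectes_altivelis	13.1	102	95.3	71916	705
Ambassidae	Ambassis_urotaenia	3.8	107	100.0	79646	744
Cichlidae	Heros_appendictulatus	20.5	102	95.3	65805	645
Cichlidae	Retroculus_xinguensis	28.8	104	97.2	58933	567
Cichlidae	Ptychochromis_grandidieri	6.1	106	99.1	77747	733
Cichlidae	Etroplus_maculatus	8.3	104	97.2	75914	730
Embiotocidae	Embiotica_jacksoni	5.0	105	98.1	78663	749
Gobiesocidae	Diademichthys_lineatus	15.1	94	87.9	74290	748
Gobiesocidae	Gobiesox_maendricus	9.5	100	93.5	74914	749
Grammatidae	Gramma_loreto	3.9	106	99.1	79574	751
Mugilidae	Mugil_cephalus	8.0	105	98.1	76200	726
Opistognathidae	Opistognathus_aurifrons	13.1	102	95.3	71916	705
Pholidichthyidae	Pholidichthys_leucotaenia	41.0	97	90.7	48818	503
Plesiopidae	Plesiops_coeruleolineatus	6.9	105	98.1	77035	734
Polycentridae	Polycentrus_schomburgki	4.1	106	99.1	79382	749
Pomacentridae	Microspathodon_bairdii	3.0	106	99.1	80210	757
Pomacentridae	Pomacentrus_nigromanus	3.4	107	100.0	80008	748
Pseudochromidae	Congrogadus_subducens	5.4	105	98.1	78329	746
Pseudochromidae	Pseudochromis_fridmani	5.1	104	97.2	79601	756
Bovichtidae	Bovichtus_diacanthus	3.9	107	100.0	79562	744
Eleginopidae	Eleginops_maclovinus	13.2	100	93.5	71885	719
Monocentridae	Monocentris_reedi	2.9	106	99.1	80413	759
Anomalopidae	Anomalops_kataptron	2.8	107	100.0	80501	752
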