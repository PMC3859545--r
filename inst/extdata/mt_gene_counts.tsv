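gene_id	gene_name	locus	length	S0	S1	S2	S3
ENSG00000210049	MT-TF	MT:577-647:1	71	4716	72194	45984	42484
ENSG00000211459	MT-RNR1	MT:648-1601:1	954	4626427	98775	54719	51139
ENSG00000210077	MT-TV	MT:1602-1670:1	69	36340	10399	6856	1215
ENSG00000210082	MT-RNR2	MT:1671-3229:1	1559	13296885	250572	1137529	153605
ENSG00000209082	MT-TL1	MT:3230-3304:1	75	86075	20917	13706	19721
ENSG00000198888	MT-ND1	MT:3307-4262:1	956	1003620	480131	557853	659073
ENSG00000210100	MT-TI	MT:4263-4331:1	69	19538	21026	11319	7338
ENSG00000210107	MT-TQ	MT:4329-4400:-1	72	26650	31551	37167	27844
ENSG00000210112	MT-TM	MT:4402-4469:1	68	53547	40780	53844	59771
ENSG00000198763	MT-ND2	MT:4470-5511:1	1042	643951	625223	928642	622441
ENSG00000210117	MT-TW	MT:5512-5579:1	68	7355	19999	8161	3780
ENSG00000210127	MT-TA	MT:5587-5655:-1	69	6825	13478	5840	3956
ENSG00000210135	MT-TN	MT:5657-5729:-1	73	8457	11923	4449	4815
ENSG00000210140	MT-TC	MT:5761-5826:-1	66	12786	7746	3790	3592
ENSG00000210144	MT-TY	MT:5826-5891:-1	66	8401	8967	4896	4065
ENSG00000198804	MT-CO1	MT:5904-7445:1	1542	414158	1257943	1669453	1633848
ENSG00000210151	MT-TS1	MT:7446-7514:-1	69	32507	12569	11010	9894
ENSG00000210154	MT-TD	MT:7518-7585:1	68	7787	7045	6504	4022
ENSG00000198712	MT-CO2	MT:7586-8269:1	684	529645	397862	485662	598293
ENSG00000210156	MT-TK	MT:8295-8364:1	70	16629	14388	13232	15576
ENSG00000228253	MT-ATP8	MT:8366-8572:1	207	61948	66353	72109	65706
ENSG00000198899	MT-ATP6	MT:8527-9207:1	681	357851	277472	294047	304636
ENSG00000198938	MT-CO3	MT:9207-9990:1	784	298920	387019	407105	435081
ENSG00000210164	MT-TG	MT:9991-10058:1	68	6289	11269	13275	11525
ENSG00000198840	MT-ND3	MT:10059-10404:1	346	86378	92634	121847	146128
ENSG00000210174	MT-TR	MT:10405-10469:1	65	8430	11341	17249	19014
ENSG00000212907	MT-ND4L	MT:10470-10766:1	297	111257	118428	203231	207225
ENSG00000198886	MT-ND4	MT:10760-12137:1	1378	404373	502675	664748	575461
ENSG00000210176	MT-TH	MT:12138-12206:1	69	10272	14951	7898	7056
ENSG00000210184	MT-TS2	MT:12207-12265:1	59	8641	6673	7713	13231
ENSG00000210191	MT-TL2	MT:12266-12336:1	71	8013	8112	9209	12015
ENSG00000198786	MT-ND5	MT:12337-14148:1	1812	318124	585691	707224	571473
ENSG00000198695	MT-ND6	MT:14149-14673:-1	525	146565	167234	175374	85557
ENSG00000210194	MT-TE	MT:14674-14742:-1	69	7417	14089	15081	13333
ENSG00000198727	MT-CYB	MT:14747-15887:1	1141	220495	447899	453336	452116
ENSG00000210195	MT-TT	MT:15888-15953:1	66	9053	52084	45617	48793
ENSG00000210196	MT-TP	MT:15956-16023:1	68	4530	31223	21717	24467
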