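bait_chr	bait_start	bait_end	bait_name	oe_chr	oe_start	oe_end	oe_name	N_reads	score
chr2	23945	24384	frag123	chr2	3240	3773	frag73	55	7.03575291857123
chr2	6775	7212	frag84	chr2	3240	3773	frag73	35	9.48812273330986
chr2	2571	2683	frag71	chr2	29100	29194	frag132	43	9.11593400128186
chr2	23945	24384	frag123	chr2	18314	19669	frag115	55	9.37884214101359
chr2	2571	2683	frag71	chr2	6775	7212	frag84	63	9.10410024039447
chr2	23945	24384	frag123	chr2	4593	5120	frag78	13	3.24168352223933
chr2	27127	27262	frag128	chr2	14062	14486	frag104	58	10.7704745111987
chr2	27127	27262	frag128	chr2	10540	11113	frag93	26	7.69528032629751
chr1	18733	18886	frag38	chr1	7958	8181	frag14	24	5.98311993991956
chr1	7958	8181	frag14	chr1	24297	24534	frag53	26	7.48069923603907
chr2	24384	24623	frag124	chr1	26844	27792	frag61	20	6.66085589886643
chr1	2320	3933	frag5	chr1	17223	17544	frag34	27	8.21187091432512
chr1	24161	24297	frag52	chr1	15621	15745	frag29	26	6.9179357662797
chr1	504	2172	frag3	chr1	12813	13588	frag23	21	7.55092515982687
chr1	504	2172	frag3	chr1	21289	22042	frag46	27	8.95180636364967
chr1	15460	15621	frag28	chr1	26192	26815	frag59	24	7.60534966364503
chr1	7958	8181	frag14	chr1	11371	11449	frag19	31	8.11384481564164
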