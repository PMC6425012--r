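locus	sentinel	proxies	genes	gwas_set
ANKFN1	rs72829754	rs56335503|0.96;rs8065311|0.95	NOG|21.00	Heel
C11orf58	rs56928337	rs78152188|0.99	TCONS_00019584|NA;TCONS_00019858|NA	Heel
CCND1	rs4980659	rs6606645|0.91	CCND1|88.53	DEXA
CRADD	rs7969076	rs7953280|0.88	SOCS2|3.78;SOCS2-AS1|0.59	Heel
DLX5	rs1724298	rs1724298|1	SHFM1|9.38	Heel
DLX6-AS1	rs17598132	rs73402679|0.94	SHFM1|9.38	Heel
DNM3	rs12041600	rs1992549|1;rs1992550|1;rs2586393|0.99;rs6694387|0.94	DNM3OS|8.92;MIR199A2|NA	Heel
EMP1	rs76243438	rs116942315|1;rs117604090|1;rs199595633|1;rs75180224|1	EMP1|30.57	Heel
EN1	rs62159864	rs62159869|0.97	TCONS_00004419|NA	Heel
EPDR1	rs1717731	rs939666|0.87	EPDR1|25.59;SFRP4|0.88	Heel
FADS2	rs174574	rs3834458|0.92	FADS1|19.09	Heel
FRZB	rs10206992	rs36090522|0.99;rs9288087|0.99	FRZB|12.92	Heel
GMDS-AS1	rs4959677	rs1010762|0.85	LINC01600|NA;TCONS_00011252|NA	Heel
GNG12-AS1	rs143243230	rs143243230|1	WLS|12.78	Heel
HOXA-AS3	rs62454420	rs62454420|1	CBX3|15.70;SKAP2|5.32	Heel
HOXA11	rs17501090	rs149457254|0.82	HIBADH|10.12;TAX1BP1|9.35	Heel
HOXC6	rs736825	rs765634|0.88	HOXC-AS1|0.34;HOXC4|0.15;HOXC5|0.36;HOXC9|8.71;SMUG1|5.16;TCONS_00020435|0.02;TCONS_00020436|NA;TCONS_00020437|0.01;TCONS_00020438|NA	DEXA
IGFBP7	rs11133474	rs11133472|0.99;rs11133474|1	IGFBP7|1445.99;IGFBP7-AS1|0.58	Heel
JAG1	rs17457340	rs141094380|0.95;rs78438678|0.95	LOC339593|NA;TCONS_l2_00016479|NA;TCONS_l2_00016480|NA;TCONS_l2_00016851|0.01	Heel
KCNE2	rs55787537	rs55787537|1	LINC00649|0.02;TCONS_00029004|NA	Heel
KIAA2012	rs62195575	rs13000317|0.82;rs13384015|0.87	CDK15|0.09;KIAA2012|NA	Heel
KIAA2018	rs1026364	rs150722690|0.90;rs16861312|0.90;rs9288983|0.90;rs9851731|0.87	ATP6V1A|21.00;NAA50|13.11	DEXA
LEKR1	rs344081	rs344088|0.97	SSR3|60.86;TIPARP|11.64;TIPARP-AS1|0.15	DEXA
LINC00880	rs56082403	rs13322435|0.98;rs56406311|0.9;rs9817452|0.9;rs9854955|0.98	LEKR1|0.08;LINC00886|0.55;SSR3|60.86;TCONS_00006285|NA;TCONS_l2_00019596|0.03;TIPARP|11.64;TIPARP-AS1|0.15	Heel
LOC101929268	rs6471752	rs72639005|0.84;rs55864946|0.84;rs72639011|0.84;rs72639012|0.84	LOC101929217|NA;SNAI2|39.39;TCONS_00014692|0.01	Heel
MAPT/WNT3	rs1864325	17:44121917:C:T|0.99;17:44231617:A:T|0.99;17:44237372:G:C|0.99;17:44245359:G:A|0.84;rs62063683|0.99;rs974291|0.99;rs974292|0.99	KANSL1|1.89;KANSL1-AS1|0.71	DEXA
MED13L	rs73200209	rs17498543|0.84	MIR4472-2|NA	DEXA
MEPE	rs6532023	rs1471401|1	SPP1|12.86	Both
MLPH	rs58057291	rs13408361|0.9;rs6722471|0.93;rs7569197|0.9;rs7571898|0.9;rs7598954|0.87;rs9287620|0.87	COL6A3|125.76;TCONS_00003518|NA	Heel
MTAP	rs7035284	rs7852691|0.98	MIR31HG|9.48	DEXA
PHLDB1	rs10790255	rs10892247|0.85	PHLDB1|11.37	Heel
PLEKHG4	rs17680862	rs8047360|0.8;rs8050375|0.8;rs114485334|0.83	B3GNT9|27.79;CES4A|0.22;FBXL8|2.05;TRADD|11.46	Heel
RERE	rs2252865	rs2708633|0.92;rs301789|0.93;rs301790|0.93;rs301791|0.93;rs301792|0.93	LOC102724552|NA;RERE|0.94	DEXA
RNU5F-1	rs2275707	rs1694593|0.96;rs1694594|0.96	SLC30A10|0.00	Heel
SFRP4	rs17236800	rs10264106|1;rs1014939|0.99;rs2167269|0.99	STARD3NL|6.44;TRG-AS1|NA	Both
SLC1A3	rs1428968	rs1428968|1	SLC1A3|0.78	Heel
SLC8A1	rs10490046	rs10490046|1	SLC8A1|3.39	Both
SLX4IP	rs6040006	rs111539884|0.88;rs74516716|0.88;rs78532542|0.88	LOC339593|NA;TCONS_l2_00016479|NA;TCONS_l2_00016480|NA;TCONS_l2_00016851|0.01	Heel
SMAD3	rs1545161	rs1545161|1;rs28587205|0.98;rs72219900|0.99	SMAD3|2.59	Both
SMAD9	rs556429	rs17217404|0.95	SMAD9|11.59	DEXA
SMG6	rs35401268	rs35401268|1	SMG6|3.19	Both
SPEN	rs6701290	rs6688051|0.93	FLJ37453|NA;SPEN|1.15;ZBTB17|6.09	Heel
SPTB	rs1957429	rs28370916|0.83	SPTB|0.02	DEXA
STARD3NL	rs6956946	rs1524068|1;rs940347|1	EPDR1|25.59;SFRP4|0.88	Both
TBPL2	rs34652660	rs12431542|0.90;rs202007979|0.89;rs4901570|0.90;rs8009706|0.90	KTN1|10.46;KTN1-AS1|0.03	DEXA
WLS	rs17482952	rs17482952|1;rs79441491|0.97	WLS|12.78	DEXA
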