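bait_chr	bait_start	bait_end	bait_name	oe_chr	oe_start	oe_end	oe_name	N_reads	score
chr2	19786	22797	bin30	chr2	0	1814	bin17	53	9.6891078366898
chr2	22797	24623	bin31	chr2	3240	4511	bin19	55	10.9910618085414
chr2	6422	7212	bin21	chr2	3240	4511	bin19	35	10.4098544386216
chr2	1814	3240	bin18	chr2	27262	29194	bin33	43	6.40069367736578
chr2	22797	24623	bin31	chr2	18213	19786	bin29	55	5.7390797259286
chr1	6332	10718	bin4	chr1	19315	20069	bin11	21	7.11420371383429
chr1	24297	26031	bin14	chr1	5352	6332	bin3	21	8.39755756594241
chr2	11956	13609	bin25	chr2	29194	30000	bin34	28	6.66200571041554
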