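variable	level	is_reference	n_cases	n_controls
prior_negative_second_level_rounds	0	1	59	62
prior_negative_second_level_rounds	ge1	0	6	4
benign_biopsies	0	1	49	57
benign_biopsies	ge1	0	14	9
first_degree_relatives_bc	0	1	56	58
first_degree_relatives_bc	ge1	0	5	8
age_menarche	le11	1	19	22
age_menarche	12-13	0	33	33
age_menarche	ge14	0	12	11
contraceptive_therapy	none_or_lt1y	1	31	29
contraceptive_therapy	1-4y	0	5	10
contraceptive_therapy	ge5y	0	28	25
smoking_habit	never	1	26	31
smoking_habit	ex	0	25	19
smoking_habit	current_or_occasional	0	11	15
birads_density	1	1	21	21
birads_density	2	0	27	34
birads_density	3or4	0	17	11
tabar_density	1	1	10	22
tabar_density	2	0	23	25
tabar_density	3	0	7	6
tabar_density	4or5	0	25	13
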