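case_id	sample_id	referral_condition	recruitment_status	first_hit_gene	first_hit_kind	first_hit_id	solved
P1	P1_P	cystic fibrosis	correctly_recruited	CFTR	small_variant	CFTR:c.1521_1523del	newly_solved
P2	P2_P	Warburg Micro syndrome	correctly_recruited	RAB3GAP1	small_variant	RAB3GAP1:c.2387_2390del	newly_solved
P3	P3_P	pseudoxanthoma elasticum	correctly_recruited	ABCC6	small_variant	ABCC6:c.2787+1G>T	newly_solved
P4	P4_P	generalised arterial calcification of infancy	correctly_recruited	ABCC6	small_variant	ABCC6:c.1769C>T	newly_solved
P5	P5_P	cystic fibrosis	correctly_recruited	CFTR	small_variant	CFTR:c.1521_1523del	newly_solved
P6	P6_P	cystic fibrosis	correctly_recruited	CFTR	small_variant	CFTR:c.1521_1523del	newly_solved
P7	P7_P	cystic fibrosis	correctly_recruited	CFTR	ROH_only		newly_solved
P8	P8_P	Jeune syndrome	correctly_recruited	DYNC2H1	small_variant	DYNC2H1:c.8348A>T	newly_solved
S01	S01_P	cystic fibrosis	correctly_recruited	GENE_S01	small_variant	GENE_S01:c.1A>T	previously_solved
S02	S02_P	cystic fibrosis	correctly_recruited	GENE_S02	small_variant	GENE_S02:c.1A>T	previously_solved
S03	S03_P	other recessive disorder	correctly_recruited	GENE_S03	small_variant	GENE_S03:c.1A>T	previously_solved
S04	S04_P	other recessive disorder	correctly_recruited	GENE_S04	small_variant	GENE_S04:c.1A>T	previously_solved
S05	S05_P	other recessive disorder	correctly_recruited	GENE_S05	small_variant	GENE_S05:c.1A>T	previously_solved
S06	S06_P	other recessive disorder	correctly_recruited	GENE_S06	small_variant	GENE_S06:c.1A>T	previously_solved
S07	S07_P	other recessive disorder	correctly_recruited	GENE_S07	small_variant	GENE_S07:c.1A>T	previously_solved
S08	S08_P	other recessive disorder	correctly_recruited	GENE_S08	small_variant	GENE_S08:c.1A>T	previously_solved
S09	S09_P	other recessive disorder	correctly_recruited	GENE_S09	small_variant	GENE_S09:c.1A>T	previously_solved
S10	S10_P	other recessive disorder	correctly_recruited	GENE_S10	small_variant	GENE_S10:c.1A>T	previously_solved
U01	U01_P	cystic fibrosis	correctly_recruited	GENE_U01	small_variant	GENE_U01:c.1A>T	unsolved
U02	U02_P	cystic fibrosis	correctly_recruited	GENE_U02	small_variant	GENE_U02:c.1A>T	unsolved
U03	U03_P	cystic fibrosis	correctly_recruited	GENE_U03	small_variant	GENE_U03:c.1A>T	unsolved
U04	U04_P	cystic fibrosis	correctly_recruited	GENE_U04	small_variant	GENE_U04:c.1A>T	unsolved
U05	U05_P	cystic fibrosis	correctly_recruited	GENE_U05	small_variant	GENE_U05:c.1A>T	unsolved
U06	U06_P	other recessive disorder	correctly_recruited	GENE_U06	small_variant	GENE_U06:c.1A>T	unsolved
U07	U07_P	other recessive disorder	correctly_recruited	GENE_U07	small_variant	GENE_U07:c.1A>T	unsolved
U08	U08_P	other recessive disorder	correctly_recruited	GENE_U08	small_variant	GENE_U08:c.1A>T	unsolved
U09	U09_P	other recessive disorder	correctly_recruited	GENE_U09	small_variant	GENE_U09:c.1A>T	unsolved
U10	U10_P	other recessive disorder	correctly_recruited	GENE_U10	small_variant	GENE_U10:c.1A>T	unsolved
U11	U11_P	other recessive disorder	correctly_recruited	GENE_U11	small_variant	GENE_U11:c.1A>T	unsolved
U12	U12_P	other recessive disorder	correctly_recruited	GENE_U12	small_variant	GENE_U12:c.1A>T	unsolved
U13	U13_P	other recessive disorder	correctly_recruited	GENE_U13	small_variant	GENE_U13:c.1A>T	unsolved
U14	U14_P	other recessive disorder	correctly_recruited	GENE_U14	small_variant	GENE_U14:c.1A>T	unsolved
U15	U15_P	other recessive disorder	correctly_recruited	GENE_U15	small_variant	GENE_U15:c.1A>T	unsolved
U16	U16_P	other recessive disorder	correctly_recruited	GENE_U16	small_variant	GENE_U16:c.1A>T	unsolved
U17	U17_P	other recessive disorder	correctly_recruited	GENE_U17	small_variant	GENE_U17:c.1A>T	unsolved
U18	U18_P	other recessive disorder	correctly_recruited	GENE_U18	small_variant	GENE_U18:c.1A>T	unsolved
U19	U19_P	other recessive disorder	correctly_recruited	GENE_U19	small_variant	GENE_U19:c.1A>T	unsolved
U20	U20_P	other recessive disorder	correctly_recruited	GENE_U20	small_variant	GENE_U20:c.1A>T	unsolved
U21	U21_P	other recessive disorder	correctly_recruited	GENE_U21	small_variant	GENE_U21:c.1A>T	unsolved
U22	U22_P	other recessive disorder	correctly_recruited	GENE_U22	small_variant	GENE_U22:c.1A>T	unsolved
U23	U23_P	other recessive disorder	correctly_recruited	GENE_U23	small_variant	GENE_U23:c.1A>T	unsolved
N01	N01_P	other recessive disorder	no_first_hit_info				unsolved
N02	N02_P	other recessive disorder	no_first_hit_info				unsolved
N03	N03_P	other recessive disorder	no_first_hit_info				unsolved
N04	N04_P	other recessive disorder	no_first_hit_info				unsolved
N05	N05_P	other recessive disorder	no_first_hit_info				unsolved
N06	N06_P	other recessive disorder	no_first_hit_info				unsolved
N07	N07_P	other recessive disorder	no_first_hit_info				unsolved
N08	N08_P	other recessive disorder	no_first_hit_info				unsolved
E01	E01_P	other recessive disorder	excluded_misrecruited	GENE_E01	small_variant	GENE_E01:c.1A>T	unsolved
E02	E02_P	other recessive disorder	excluded_misrecruited	GENE_E02	small_variant	GENE_E02:c.1A>T	unsolved
E03	E03_P	other recessive disorder	excluded_misrecruited	GENE_E03	small_variant	GENE_E03:c.1A>T	unsolved
E04	E04_P	other recessive disorder	excluded_misrecruited	GENE_E04	small_variant	GENE_E04:c.1A>T	unsolved
E05	E05_P	other recessive disorder	excluded_data_quality	GENE_E05	small_variant	GENE_E05:c.1A>T	unsolved
E06	E06_P	other recessive disorder	excluded_data_quality	GENE_E06	small_variant	GENE_E06:c.1A>T	unsolved
E07	E07_P	other recessive disorder	excluded_data_quality	GENE_E07	small_variant	GENE_E07:c.1A>T	unsolved
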