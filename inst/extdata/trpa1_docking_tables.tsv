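table	ligand	target_form	dg	nha	ei	d_best	rmsd_best	aa_match	rank_best	d_covalent
covalent_fitted	JT010	holo	-84.1	23	3.66	NA	2.28	100	1/3	1.8
covalent_fitted	BITC	holo	-77.7	10	7.77	NA	2.05	100	1/3	1.8
covalent_fitted	BODIPY	holo	-44.3	22	2.01	NA	3.87	100	1/3	1.8
covalent_fitted	JT010	apo_no_loop	-77.4	23	3.36	NA	6.82	100	1/5	1.8
covalent_fitted	BITC	apo_no_loop	-73.8	10	7.38	NA	4.75	60	1/5	1.8
covalent_fitted	BODIPY	apo_no_loop	-43.1	22	1.96	NA	6.55	66.6	1/5	1.8
prereq_fitted	JT010	holo	-46.1	23	NA	3.6	NA	100	10/10	NA
prereq_fitted	BITC	holo	-32.4	10	NA	4.0	NA	100	1/10	NA
prereq_fitted	BODIPY	holo	-13.7	22	NA	8.7	NA	100	8/10	NA
prereq_fitted	JT010	apo_no_loop	-33.4	23	NA	3.5	NA	100	3/5	NA
prereq_fitted	BITC	apo_no_loop	-26.7	10	NA	3.9	NA	60	1/5	NA
prereq_fitted	BODIPY	apo_no_loop	0.5	22	NA	3.3	NA	33.3	4/5	NA
prereq_autodock	JT010	holo	-6.8	23	NA	3.6	NA	100	1/5	NA
prereq_autodock	BITC	holo	-3.8	10	NA	6.5	NA	80	1/1	NA
prereq_autodock	BODIPY	holo	-5.9	22	NA	4.0	NA	66	4/4	NA
prereq_autodock	JT010	apo_no_loop	-5.16	23	NA	7.5	NA	50	1/3	NA
prereq_autodock	BITC	apo_no_loop	-3.74	10	NA	7.2	NA	40	1/2	NA
prereq_autodock	BODIPY	apo_no_loop	-5.26	22	NA	7.3	NA	0	3/5	NA
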