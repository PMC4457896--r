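patient_id	edss_at_lp	delta_edss	relapse_count	dmt_2y	dmt_5y	class_2y	class_5y
MS25	6	0	0	none	none	PP	PP
MS26	1	1	1	I	death	M	death
MS27	1	2.5	4	II	II	H	H
MS28	1.5	5	3	I	II	M	H
MS29	6	0	3	II	II	H	H
MS30	1	0	1	I	I	M	M
MS31	0	1	3	none	I	L	M
MS32	1.5	0.5	1	I	I	M	M
MS33	0	1	2	I	I	M	M
MS34	0	0	0	none	none	L	L
MS35	1	1	2	I	I	M	M
MS36	1	0	0	none	none	L	L
MS37	0	1	0	I	I	M	M
MS38	1	0	2	I	I	M	M
MS39	1.5	0	0	none	none	LB	LB
MS40	1	0	1	none	none	LB	LB
MS41	3.5	0	?	lost	lost	lost	lost
MS42	0	1	1	I	I	M	M
MS43	4	0	?	I	I	M	M
MS44	2	0	3	II	II	H	H
MS45	0	0	0	none	none	L	L
MS46	0	0	2	I	I	M	M
MS47	2	0	4	II	II	H	H
MS48	NA	NA	?	no_MS	no_MS	no_MS	no_MS
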