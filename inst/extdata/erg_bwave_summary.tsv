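species	adaptation	intensity_log	condition	mean_uv	sem_uv	n
degu	scotopic	-0.88	control	9.8	2.0	6
degu	scotopic	-0.88	blocker	12.4	4.7	6
degu	scotopic	0.52	control	38.4	11.4	6
degu	scotopic	0.52	blocker	38.9	10.0	6
degu	scotopic	1.82	control	105.1	23.4	6
degu	scotopic	1.82	blocker	57.8	16.0	6
rat	scotopic	-0.88	control	136.3	45.9	4
rat	scotopic	-0.88	blocker	86.0	39.1	4
rat	scotopic	0.52	control	526.7	72.9	4
rat	scotopic	0.52	blocker	276.2	79.9	4
rat	scotopic	1.82	control	569.7	78.5	4
rat	scotopic	1.82	blocker	272.4	88.85	4
degu	photopic	1.03	control	2.8	1.2	4
degu	photopic	1.03	blocker	10.7	1.5	4
degu	photopic	1.63	control	17.4	1.9	4
degu	photopic	1.63	blocker	44.2	2.2	4
degu	photopic	2.33	control	47.2	7.1	4
degu	photopic	2.33	blocker	97.7	7.8	4
rat	photopic	1.03	control	6.5	2.1	4
rat	photopic	1.03	blocker	3.5	3.2	4
rat	photopic	1.63	control	23.2	6.3	4
rat	photopic	1.63	blocker	8.1	3.9	4
rat	photopic	2.33	control	68.0	16.4	4
rat	photopic	2.33	blocker	25.7	14.2	4
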