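fibre_diameter_um	internode_um	node_length_um	node_diameter_um	mysa_length_um	mysa_diameter_um	flut_length_um	flut_diameter_um	stin_n	stin_diameter_um	lamellae	space_node_um	space_mysa_um	space_flut_um	space_stin_um
5.7	500	1	1.9	3	1.9	35	3.4	6	3.4	80	0.002	0.002	0.004	0.004
7.3	750	1	2.4	3	2.4	38	4.6	6	4.6	100	0.002	0.002	0.004	0.004
8.7	1000	1	2.8	3	2.8	40	5.8	6	5.8	110	0.002	0.002	0.004	0.004
10.0	1150	1	3.3	3	3.3	46	6.9	6	6.9	120	0.002	0.002	0.004	0.004
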