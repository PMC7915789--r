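node	region	feature_class	label
1	bankssts	thickness	bankssts_thickness
2	caudalanteriorcingulate	thickness	caudalanteriorcingulate_thickness
3	caudalmiddlefrontal	thickness	caudalmiddlefrontal_thickness
4	cuneus	thickness	cuneus_thickness
5	entorhinal	thickness	entorhinal_thickness
6	frontalpole	thickness	frontalpole_thickness
7	fusiform	thickness	fusiform_thickness
8	inferiorparietal	thickness	inferiorparietal_thickness
9	inferiortemporal	thickness	inferiortemporal_thickness
10	insula	thickness	insula_thickness
11	isthmuscingulate	thickness	isthmuscingulate_thickness
12	lateraloccipital	thickness	lateraloccipital_thickness
13	lateralorbitofrontal	thickness	lateralorbitofrontal_thickness
14	lingual	thickness	lingual_thickness
15	medialorbitofrontal	thickness	medialorbitofrontal_thickness
16	middletemporal	thickness	middletemporal_thickness
17	paracentral	thickness	paracentral_thickness
18	parahippocampal	thickness	parahippocampal_thickness
19	parsopercularis	thickness	parsopercularis_thickness
20	parsorbitalis	thickness	parsorbitalis_thickness
21	parstriangularis	thickness	parstriangularis_thickness
22	pericalcarine	thickness	pericalcarine_thickness
23	postcentral	thickness	postcentral_thickness
24	posteriorcingulate	thickness	posteriorcingulate_thickness
25	precentral	thickness	precentral_thickness
26	precuneus	thickness	precuneus_thickness
27	rostralanteriorcingulate	thickness	rostralanteriorcingulate_thickness
28	rostralmiddlefrontal	thickness	rostralmiddlefrontal_thickness
29	superiorfrontal	thickness	superiorfrontal_thickness
30	superiorparietal	thickness	superiorparietal_thickness
31	superiortemporal	thickness	superiortemporal_thickness
32	supramarginal	thickness	supramarginal_thickness
33	temporalpole	thickness	temporalpole_thickness
34	transversetemporal	thickness	transversetemporal_thickness
35	bankssts	area	bankssts_area
36	caudalanteriorcingulate	area	caudalanteriorcingulate_area
37	caudalmiddlefrontal	area	caudalmiddlefrontal_area
38	cuneus	area	cuneus_area
39	entorhinal	area	entorhinal_area
40	frontalpole	area	frontalpole_area
41	fusiform	area	fusiform_area
42	inferiorparietal	area	inferiorparietal_area
43	inferiortemporal	area	inferiortemporal_area
44	insula	area	insula_area
45	isthmuscingulate	area	isthmuscingulate_area
46	lateraloccipital	area	lateraloccipital_area
47	lateralorbitofrontal	area	lateralorbitofrontal_area
48	lingual	area	lingual_area
49	medialorbitofrontal	area	medialorbitofrontal_area
50	middletemporal	area	middletemporal_area
51	paracentral	area	paracentral_area
52	parahippocampal	area	parahippocampal_area
53	parsopercularis	area	parsopercularis_area
54	parsorbitalis	area	parsorbitalis_area
55	parstriangularis	area	parstriangularis_area
56	pericalcarine	area	pericalcarine_area
57	postcentral	area	postcentral_area
58	posteriorcingulate	area	posteriorcingulate_area
59	precentral	area	precentral_area
60	precuneus	area	precuneus_area
61	rostralanteriorcingulate	area	rostralanteriorcingulate_area
62	rostralmiddlefrontal	area	rostralmiddlefrontal_area
63	superiorfrontal	area	superiorfrontal_area
64	superiorparietal	area	superiorparietal_area
65	superiortemporal	area	superiortemporal_area
66	supramarginal	area	supramarginal_area
67	temporalpole	area	temporalpole_area
68	transversetemporal	area	transversetemporal_area
69	amygdala	volume	amygdala_volume
70	caudate	volume	caudate_volume
71	hippocampus	volume	hippocampus_volume
72	pallidum	volume	pallidum_volume
73	putamen	volume	putamen_volume
74	thalamus	volume	thalamus_volume
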