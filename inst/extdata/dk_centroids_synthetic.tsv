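region	x	y	z
lh_bankssts	-54	-45	8
lh_caudalanteriorcingulate	-5	20	30
lh_caudalmiddlefrontal	-38	15	45
lh_cuneus	-8	-80	28
lh_entorhinal	-25	-10	-30
lh_frontalpole	-10	60	-10
lh_fusiform	-36	-50	-18
lh_inferiorparietal	-42	-62	40
lh_inferiortemporal	-50	-40	-22
lh_insula	-36	0	2
lh_isthmuscingulate	-8	-45	25
lh_lateraloccipital	-30	-88	5
lh_lateralorbitofrontal	-25	35	-15
lh_lingual	-15	-70	-5
lh_medialorbitofrontal	-8	40	-18
lh_middletemporal	-58	-30	-10
lh_paracentral	-8	-25	60
lh_parahippocampal	-25	-35	-15
lh_parsopercularis	-48	15	15
lh_parsorbitalis	-45	35	-8
lh_parstriangularis	-48	28	8
lh_pericalcarine	-10	-82	8
lh_postcentral	-42	-25	50
lh_posteriorcingulate	-6	-30	38
lh_precentral	-40	-10	48
lh_precuneus	-10	-58	40
lh_rostralanteriorcingulate	-6	35	10
lh_rostralmiddlefrontal	-32	45	25
lh_superiorfrontal	-12	25	55
lh_superiorparietal	-25	-60	55
lh_superiortemporal	-55	-15	0
lh_supramarginal	-52	-40	35
lh_temporalpole	-32	12	-35
lh_transversetemporal	-45	-22	10
rh_bankssts	54	-45	8
rh_caudalanteriorcingulate	5	20	30
rh_caudalmiddlefrontal	38	15	45
rh_cuneus	8	-80	28
rh_entorhinal	25	-10	-30
rh_frontalpole	10	60	-10
rh_fusiform	36	-50	-18
rh_inferiorparietal	42	-62	40
rh_inferiortemporal	50	-40	-22
rh_insula	36	0	2
rh_isthmuscingulate	8	-45	25
rh_lateraloccipital	30	-88	5
rh_lateralorbitofrontal	25	35	-15
rh_lingual	15	-70	-5
rh_medialorbitofrontal	8	40	-18
rh_middletemporal	58	-30	-10
rh_paracentral	8	-25	60
rh_parahippocampal	25	-35	-15
rh_parsopercularis	48	15	15
rh_parsorbitalis	45	35	-8
rh_parstriangularis	48	28	8
rh_pericalcarine	10	-82	8
rh_postcentral	42	-25	50
rh_posteriorcingulate	6	-30	38
rh_precentral	40	-10	48
rh_precuneus	10	-58	40
rh_rostralanteriorcingulate	6	35	10
rh_rostralmiddlefrontal	32	45	25
rh_superiorfrontal	12	25	55
rh_superiorparietal	25	-60	55
rh_superiortemporal	55	-15	0
rh_supramarginal	52	-40	35
rh_temporalpole	32	12	-35
rh_transversetemporal	45	-22	10
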