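name	network	x	y	z	radius_mm	mask_path	note	synthetic
lM1	MVN	-38	-22	54	7.5	NA	Left primary motor cortex (Area 4)	TRUE
rM1	MVN	38	-22	54	7.5	NA	Right primary motor cortex (Area 4)	TRUE
lSMA	MVN	-6	-8	58	7.5	NA	Left supplementary motor area (Area 6)	TRUE
rSMA	MVN	6	-8	58	7.5	NA	Right supplementary motor area (Area 6)	TRUE
lIPS	MVN	-25	-57	46	7.5	NA	Left intra-parietal sulcus	FALSE
rIPS	MVN	25	-57	46	7.5	NA	Right intra-parietal sulcus	FALSE
lFEF	MVN	-25	-13	50	7.5	NA	Left frontal eye field	FALSE
rFEF	MVN	25	-13	50	7.5	NA	Right frontal eye field	FALSE
lLP	DMN	-45	-67	36	7.5	NA	Left lateral parietal region	FALSE
rLP	DMN	45	-67	36	7.5	NA	Right lateral parietal region	FALSE
PCC	DMN	-5	-49	40	7.5	NA	Posterior cingulate cortex	FALSE
MPF	DMN	-1	47	-4	7.5	NA	Medial prefrontal cortex	FALSE
lV1	control	-8	-88	2	7.5	NA	Left primary visual cortex (Area 17)	TRUE
rV1	control	8	-88	2	7.5	NA	Right primary visual cortex (Area 17)	TRUE
lA1	control	-47	-22	10	7.5	NA	Left auditory cortex (Areas 41/42)	TRUE
rA1	control	47	-22	10	7.5	NA	Right auditory cortex (Areas 41/42)	TRUE
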