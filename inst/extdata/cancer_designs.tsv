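cancer	study	n_cases	n_controls
Colorectal (all)	GAME-ON	5100	4831
Colorectal (all)	GECCO	11488	11679
Colorectal (women)	GECCO	6132	6380
Colorectal (men)	GECCO	5356	5297
Colon	GECCO	7678	11679
Rectal	GECCO	2783	11679
Distal colon	GECCO	3354	11679
Proximal colon	GECCO	4185	11679
Breast (all)	DRIVE	15748	18084
Breast (ER-)	DRIVE	4939	13128
Prostate (all)	PRACTICAL	22898	23054
Prostate (all)	GAME-ON	14159	12712
Prostate (aggressive)	GAME-ON	4445	12724
Ovarian (all)	FOCI	4369	9123
Ovarian (clear-cell)	FOCI	356	9123
Ovarian (endometrioid)	FOCI	715	9123
Ovarian (serous)	FOCI	2556	9123
Lung (all)	TRICL-ILCCO	12537	17285
Lung (adenocarcinoma)	TRICL-ILCCO	3804	16289
Lung (squamous)	TRICL-ILCCO	3546	16434
Pancreatic (all)	PanScan1	1896	1939
Neuroblastoma (all)	Capasso	1627	3254
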