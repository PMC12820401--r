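nutrient_name	metabolite_id	group
Glucose	glc_D	carbohydrate
Fructose	fru	carbohydrate
Sucrose	sucr	carbohydrate
Starch, resolved	strch	carbohydrate
Fiber, cellulose	cellul	fibre
Alanine	ala_L	protein
Leucine	leu_L	protein
Glutamic acid	glu_L	protein
Glycine	gly	protein
SFA 18:0	ocdca	lipid
PUFA 18:2	lnlc	lipid
SFA 16:0	hdca	lipid
Retinol	retinol	other
Water	h2o	other
Ethanol	etoh	alcohol
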