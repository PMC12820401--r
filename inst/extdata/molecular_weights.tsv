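metabolite_id	mw
glc_D	180.156
fru	180.156
sucr	342.297
strch	162.141
cellul	162.141
ala_L	89.093
leu_L	131.173
glu_L	147.129
gly	75.067
ocdca	284.484
lnlc	280.447
hdca	256.43
retinol	286.459
h2o	18.015
etoh	46.069
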