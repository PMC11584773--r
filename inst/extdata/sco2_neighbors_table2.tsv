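feature_id	annotation	node_type	rho
Solyc06g053710.3	ethylene receptor homolog (ETR4)	transcript	−0.971428571
Solyc09g091270.3	cotton fiber protein	transcript	−0.964285714
Solyc01g105010.3	Non-specific lipid-transfer protein-like protein	transcript	−0.960714286
Solyc02g087740.3	Plant cysteine oxidase 2	transcript	−0.957142857
Solyc07g018070.4	Double Clp-N motif-containing P-loop nucleoside triphosphate hydrolases superfamily protein	transcript	−0.957142857
Solyc03g119390.4	bHLH transcription factor 026	transcript	−0.95
Solyc01g106380.2	hypothetical protein	transcript	0.95
Solyc01g110270.3	RNA-binding CRS1 / YhbY (CRM) domain protein	transcript	0.95
Solyc03g082560.3	Aldo-keto reductase/ oxidoreductase	transcript	0.95
Solyc12g094630.2	Low-density receptor-like protein	transcript	0.95
Solyc01g105340.4	Chaperone protein DnaJ	transcript	0.953571429
Solyc02g071190.4	Carboxyl-terminal-processing protease-like protein	transcript	0.953571429
Solyc03g026200.4	protein COFACTOR ASSEMBLY OF COMPLEX C SUBUNIT B CCB2, chloroplastic	transcript	0.953571429
Solyc03g044470.4	red chlorophyll catabolite reductase	transcript	0.953571429
Solyc03g062710.4	protein NDH-DEPENDENT CYCLIC ELECTRON FLOW 5	transcript	0.953571429
Solyc12g096100.2	Protein PAM68, chloroplastic	transcript	0.953571429
A0A3Q7HR44	NA	protein	0.953571429
Solyc00g500066.1	Photosystem I assembly protein Ycf4	transcript	0.957142857
Solyc03g063240.3	Pyridoxamine 5'-phosphate oxidase-related FMN-binding protein	transcript	0.957142857
Solyc03g124060.3	Polyketide cyclase/dehydrase and lipid transport superfamily protein	transcript	0.957142857
Solyc08g075100.4	Initiation factor 4 F subunit (DUF1350)	transcript	0.957142857
Solyc11g007130.2	Major facilitator superfamily	transcript	0.957142857
A0A3Q7H1X6	NA	protein	0.967432647
Solyc07g064100.1	Chlororespiratory reduction 41	transcript	0.967857143
Solyc12g009440.2	DnaJ/Hsp40 cysteine-rich domain superfamily protein	transcript	0.967857143
A0A3Q7G7J3	NA	protein	0.967857143
Solyc05g006110.3	Serine/Threonine-kinase	transcript	0.971428571
Solyc10g005870.4	Peptidylprolyl isomerase	transcript	0.971428571
Solyc09g010110.3	Chaperone protein dnaJ-related protein	transcript	0.975
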