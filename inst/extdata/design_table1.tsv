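accession	study	assay	background	groups	comparisons
PRJNA118709	Kambris et al. 2009	Array	2 and 15 days-old female whole bodies from laboratory lines	A|Line PGYP1 (wMelPop-infected)|infected|whole body; B|Line PGYP1.tet (cleared)|uninfected|whole body	A vs B
E-MEXP-2931	Rances et al. 2012	Array	8 days-old female whole bodies from laboratory lines	A|Line PGYP1 (wMelPop-infected)|infected|whole body; B|Line PGYP1.tet (cleared)|uninfected|whole body; C|Line MGYP2 (wMel-infected)|infected|whole body; D|Line MGYP2.tet (cleared)|uninfected|whole body	A vs B; C vs D
E-MEXP-2907	Ye et al. 2013	Array	15 days-old female tissues from laboratory lines	A|Line PGYP1, head|infected|head; B|Line PGYP1.tet, head|uninfected|head; C|Line PGYP1, muscle|infected|muscle; D|Line PGYP1.tet, muscle|uninfected|muscle	A vs B; C vs D
PRJNA867516	Wimalasiri-Yapa et al. 2023	RNASeq	4 days-old female whole bodies from natural populations with given wMel release histories	A|wMel released in 2011|infected|whole body; B|wMel released in 2013/14|infected|whole body; C|wMel released in 2017|infected|whole body; D|No release|uninfected|whole body	A vs D; B vs D; C vs D
PRJNA949154	Boehm et al. 2023	RNASeq	7 to 13 days-old female tissues from laboratory lines, at given days post blood feeding (dpf)	A|Line COL.wMel, carcass, 4 dpf|infected|carcass; B|Line COL.tet, carcass, 4 dpf|uninfected|carcass; C|Line COL.wMel, carcass, 7 dpf|infected|carcass; D|Line COL.tet, carcass, 7 dpf|uninfected|carcass; E|Line COL.wMel, midgut, 4 dpf|infected|midgut; F|Line COL.tet, midgut, 4 dpf|uninfected|midgut; G|Line COL.wMel, midgut, 7 dpf|infected|midgut; H|Line COL.tet, midgut, 7 dpf|uninfected|midgut	A vs B; C vs D; E vs F; G vs H
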