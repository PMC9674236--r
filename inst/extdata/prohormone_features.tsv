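accession	name	start	end	kind	amidated
P01275	Signal	1	20	signal	FALSE
P01275	Glicentin	21	89	peptide	FALSE
P01275	GRPP	21	50	peptide	FALSE
P01275	Glucagon	53	81	peptide	FALSE
P01275	Oxyntomodulin	53	89	peptide	FALSE
P01275	GLP-1(7-37)	98	128	peptide	FALSE
P01275	GLP-1(7-36)	98	127	peptide	TRUE
P01275	IP-2	131	145	propeptide	FALSE
P01275	GLP-2	146	178	peptide	FALSE
SYNSST	Signal	1	20	signal	FALSE
SYNSST	SST-pep1	21	31	peptide	FALSE
SYNSST	SST-pep2	34	44	peptide	FALSE
SYNSST	SST-pep3	47	58	peptide	FALSE
SYNSST	SST-pep4	61	72	peptide	FALSE
SYNSST	SST-pep4	61	71	peptide	TRUE
SYNNPW	Signal	1	20	signal	FALSE
SYNNPW	NPW-pep1	21	32	peptide	FALSE
SYNNPW	NPW-pep2	35	46	peptide	FALSE
SYNNPW	NPW-pep3	49	60	peptide	FALSE
SYNNPW	NPW-pep3	49	59	peptide	TRUE
SYNNPW	NPW-pep4	63	73	peptide	FALSE
SYNPPY	Signal	1	20	signal	FALSE
SYNPPY	PPY-pep1	21	35	peptide	FALSE
SYNPPY	PPY-pep2	38	51	peptide	FALSE
SYNPPY	PPY-pep2	38	50	peptide	TRUE
SYNPPY	PPY-pep3	54	65	peptide	FALSE
SYNPPY	PPY-pep4	68	76	peptide	FALSE
SYNMLN	Signal	1	20	signal	FALSE
SYNMLN	MLN-pep1	21	31	peptide	FALSE
SYNMLN	MLN-pep2	34	45	peptide	FALSE
SYNMLN	MLN-pep3	48	59	peptide	FALSE
SYNMLN	MLN-pep3	48	58	peptide	TRUE
SYNMLN	MLN-pep4	62	72	peptide	FALSE
SYNSCG2	Signal	1	20	signal	FALSE
SYNSCG2	SCG2-pep1	21	32	peptide	FALSE
SYNSCG2	SCG2-pep2	35	46	peptide	FALSE
SYNSCG2	SCG2-pep3	49	60	peptide	FALSE
SYNSCG2	SCG2-pep4	63	74	peptide	FALSE
SYNSCG2	SCG2-pep5	77	87	peptide	FALSE
SYNCHGA	Signal	1	20	signal	FALSE
SYNCHGA	CHGA-pep1	21	32	peptide	FALSE
SYNCHGA	CHGA-pep2	35	46	peptide	FALSE
SYNCHGA	CHGA-pep3	49	60	peptide	FALSE
SYNCHGA	CHGA-pep3	49	59	peptide	TRUE
SYNCHGA	CHGA-pep4	63	73	peptide	FALSE
SYNVGF	Signal	1	20	signal	FALSE
SYNVGF	VGF-pep1	21	32	peptide	FALSE
SYNVGF	VGF-pep2	35	46	peptide	FALSE
SYNVGF	VGF-pep3	49	60	peptide	FALSE
SYNVGF	VGF-pep3	49	59	peptide	TRUE
SYNVGF	VGF-pep4	63	73	peptide	FALSE
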