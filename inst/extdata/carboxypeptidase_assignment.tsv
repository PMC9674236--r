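accession	carboxypeptidase
P01275	CPE
SYNSST	CPB1
SYNNPW	CPB1
SYNPPY	CPB1
SYNMLN	CPE
SYNSCG2	CPE
SYNCHGA	CPE
SYNVGF	CPE
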