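>SYNSST|SST synthetic prohormone (architecture-realistic construct)
MLSAELWTSCLLALPVLAGQNAEPSMDLTHEKRTPNDFESHLIVRRNQFTWDSHEMNEKK
WDEMSANTQLIG
>SYNNPW|NPW synthetic prohormone (architecture-realistic construct)
MGALSVAWLCLTAFPELSHAYAPEWTDNHMSQRKGDLNSEQWFTHMKRSPDYTMEHWNQG
RRFNDLSTEWHQM
>SYNPPY|PPY synthetic prohormone (architecture-realistic construct)
MATLVCLLALSAMAVSEAHQAPLEPVYGDNATSEQKKYINMLTQYESHDLGKRSNWEDQT
FHMLVRKEDNSTWQHF
>SYNMLN|MLN synthetic prohormone (architecture-realistic construct)
MVSEFACLWLIVSSLTEAGQFVPIFTYGELQKRTAEDLSNQHWMFRREDMNSHWTLFQGK
KSQNDEWFTHLM
>SYNSCG2|SCG2 synthetic prohormone (architecture-realistic construct)
MLDSASLWETCLVSLLAFHQTPQESMNDWHFLRRSGHMDFNEQTWLKRATSDWENHMFLQ
RKNAPDESWHTMGLKKEQWSNDFHTML
>SYNCHGA|CHGA synthetic prohormone (architecture-realistic construct)
MHSTAVLSLECLASTFEVHGLPVNSEDMQHTWKKEDSLVAQNTHFMRRWSMEDLNTQHFG
KRHFDQSWENMTL
>SYNVGF|VGF synthetic prohormone (architecture-realistic construct)
MSWPLAVCLLSATFAEHSGQAPPGHSDNEWTMRRQPNEWDTSHFMLRKTLQDHWSENFMG
KKQHWTENDSMFL
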