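peptide	label
IVFFVV	1
LVVILI	1
TTQVVI	1
IIVFFC	1
FQENLS	1
VGYVFR	1
LQWVTY	1
CKLVVF	1
VIWTIV	1
QLAFFI	1
VFWCMI	1
YNFIIF	1
CAQCVF	1
CLCLAW	1
FCILCQ	1
FIAVFI	1
VLYLLI	1
VVTGCR	1
TCILIF	1
CLRLLW	1
KAAQMI	1
VIIQYI	1
FVFFVC	1
IVVGIF	1
VITALV	1
FIVWVA	0
FTNDAQ	0
YPTRAR	0
DTSPIQ	0
DIPNNI	0
SFGHYW	0
DHIKFT	0
DRASDY	0
GPVYVW	0
KWDETF	0
YYNMHL	0
GVALQV	0
YVVNIE	0
LSSQAY	0
PSQFYS	0
FEMRRE	0
SVIQEG	0
VFRWFG	0
LSYYIW	0
ICDWYW	0
KYYGAK	0
IAQQWE	0
FTNEMP	0
TNDIQW	0
AGYQTW	0
EMYLFM	0
NCHIQG	0
LLDMHE	0
GVHIES	0
TENRQG	0
SYTYSF	0
DGPWFF	0
LEQQLY	0
AWRQTW	0
KTYLRH	0
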