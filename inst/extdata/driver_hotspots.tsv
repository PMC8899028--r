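gene	hgvs_p
EGFR	p.L858R
EGFR	p.T790M
EGFR	p.S768I
EGFR	p.L861Q
EGFR	p.G719A
EGFR	p.G719C
EGFR	p.G719S
EGFR	p.E746_A750del
EGFR	p.L747_T751del
EGFR	p.L747_P753delinsS
EGFR	p.C797S
KRAS	p.G12C
KRAS	p.G12D
KRAS	p.G12V
KRAS	p.G12A
KRAS	p.G12S
KRAS	p.G12R
KRAS	p.G13D
KRAS	p.Q61H
KRAS	p.Q61L
BRAF	p.V600E
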