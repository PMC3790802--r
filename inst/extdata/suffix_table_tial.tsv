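suffix	tag	freq_1	freq_n
l	DB	40	120
l	VVI	60	180
l	II	30	90
l	CS	25	75
l	VM	20	60
l	NN	500	1500
l	RR	80	240
l	NNP	45	135
l	PND	15	45
l	JJ	400	1200
l	VVB	70	210
l	DD	35	105
al	VVI	20	60
al	NN	150	450
al	RR	30	90
al	JJ	180	540
al	VVB	25	75
ial	NN	40	120
ial	JJ	60	180
tial	NN	12	36
tial	JJ	25	75
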