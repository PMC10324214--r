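species	genome_size_gb
Bufo gargarizans	4.5
Eleutherodactylus coqui	2.8
Engystomops pustulosus	2.6
Hymenochirus boettgeri	3.2
Limnodynastes dumerilii	2.4
Lithobates catesbeianus	6.3
Nanorana parkeri	2.1
Rana temporaria	4.1
Xenopus laevis	2.7
Xenopus tropicalis	1.5
Quasipaa spinosa	2.6
Rhinella marina	2.6
Spea multiplicata	1.1
Ranitomeya imitator	6.8
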