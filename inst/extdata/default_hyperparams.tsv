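algorithm	boundary_kind	parameter	value
wsvm	initiation	cost	0.1895
wsvm	initiation	gamma	0.0625
wsvm	termination	cost	0.5743
wsvm	termination	gamma	0.1895
welm	initiation	n_hidden	2000
welm	initiation	C	9300
welm	termination	n_hidden	1600
welm	termination	C	5100
rf	initiation	n_trees	160
rf	initiation	mtry	80
rf	termination	n_trees	140
rf	termination	mtry	50
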