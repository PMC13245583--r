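family	region	p
oef	wb	0.002
oef	gm	0.002
oef	wm	0.003
oef	mtl	0.011
oef	hc	0.001
oef	ag	0.001
oef	fl	0.028
oef	pl	0.004
oef	thl	0.002
oef	occ	0.009
oef	str	0.001
cbf	wb	0.011
cbf	gm	0.028
cbf	wm	0.425
cbf	mtl	0.001
cbf	hc	0.011
cbf	ag	0.202
cbf	fl	0.002
cbf	pl	0.001
cbf	thl	0.018
cbf	occ	0.004
cbf	str	0.019
cmro2	wb	0.537
cmro2	gm	0.317
cmro2	wm	0.325
cmro2	mtl	0.365
cmro2	hc	0.319
cmro2	ag	0.011
cmro2	fl	0.098
cmro2	pl	0.057
cmro2	thl	0.734
cmro2	occ	0.079
cmro2	str	0.945
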