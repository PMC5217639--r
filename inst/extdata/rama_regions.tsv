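region	class	phi_min	phi_max	psi_min	psi_max
beta	favored	-170	-50	90	175
alphaR	favored	-100	-30	-67	-7
alphaL	favored	40	80	20	80
beta	allowed	-180	-40	70	180
beta_wrap	allowed	-180	-40	-180	-165
alphaR	allowed	-120	-20	-90	10
alphaL	allowed	20	100	0	100
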