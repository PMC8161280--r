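# NTA particle numbers (1e9/mL) and DLS diameters (nm) of plasma EV fractions.
# The fc diameter is reported as "<50" nm and is evaluated at 50 nm.
fraction	group	particle_count	diameter
EV5	CONTROL	414	500
EV5	POOL_A	978	500
EV5	POOL_B	3029	500
EV12	CONTROL	1494	200
EV12	POOL_A	3206	200
EV12	POOL_B	16332	200
EV120	CONTROL	960	100
EV120	POOL_A	2014	100
EV120	POOL_B	2817	100
FC	CONTROL	1116	50
FC	POOL_A	2235	50
FC	POOL_B	662	50
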