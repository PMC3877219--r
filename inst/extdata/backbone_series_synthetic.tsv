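# Backbone amide proton shift: truncated 2-D cosine series over (phi, psi).
# Synthetic parameterization (realistic magnitudes; original fit not published).
# Columns: kphi kpsi basis coeff; basis letters select cos/sin per axis.
kphi	kpsi	basis	coeff
0	0	cc	4.6
1	0	cc	0.55
0	1	cc	-0.45
1	0	sc	0.3
0	1	cs	-0.35
1	1	cc	0.25
1	1	ss	-0.4
2	0	cc	0.12
0	2	cc	0.18
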