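# Point-dipole ring-current intensity factors per aromatic ring type
# (dimensionless, benzene = 1). Synthetic defaults on the literature scale.
kind	intensity
PHE6	1
TYR6	0.81
TRP5	0.9
TRP6	1.04
HIS5	0.68
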