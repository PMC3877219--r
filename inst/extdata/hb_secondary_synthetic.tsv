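# Secondary hydrogen-bond perturbation (bond accepted by the amide group's
# own carbonyl oxygen): delta = exp(-k*r)*(a*cos^2(theta_HOC)+b) [ppm].
# Synthetic coefficients.
param	value
k	2.2
a	30
b	18
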