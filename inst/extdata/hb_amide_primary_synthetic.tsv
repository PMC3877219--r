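# Primary hydrogen-bond shift perturbation, amide-amide closed form:
# delta = exp(-k*r_HO) * (a*cos^2(theta_HOC) + b)  [ppm; r in Angstrom].
# none_value is the fixed solvent-exposed (water-model) term in ppm.
# Synthetic coefficients; functional form exponential x angular.
param	value
k	2
a	120
b	60
none_value	2.07
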