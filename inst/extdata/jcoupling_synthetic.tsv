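# Trans-hydrogen-bond h3J(NC') closed form:
# J = -A*exp(-k*(r_HO-r0))*cos^2(theta1)*(p*cos^2(theta2)+q)  [Hz],
# theta1 = N-H...O angle, theta2 = H...O=C angle.
# Exponential-decay form; synthetic coefficients on the literature scale.
param	value
A	0.9
k	3.2
r0	1.76
p	0.2
q	0.8
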