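# Tertiary polarization increments (ppm) added when the primary/secondary
# hydrogen-bond partner amide is itself hydrogen bonded. Synthetic values.
situation	value
PRIMARY_PARTNER_BONDED	0.25
SECONDARY_PARTNER_BONDED	0.12
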