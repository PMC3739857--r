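# SYNTHETIC best-effort anaerobic minimal medium: as the aerobic minimal
# glucose medium but with the oxygen exchange closed to uptake.
# Override for models with other exchange identifiers.
reaction_id	lower_bound	upper_bound
r_1714	-10	Inf
r_1992	0	Inf
r_1654	-Inf	Inf
r_2005	-Inf	Inf
r_2060	-Inf	Inf
r_1832	-Inf	Inf
r_2100	-Inf	Inf
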