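# SYNTHETIC best-effort reconstruction of a glucose-limited aerobic minimal
# medium for the consensus yeast network (the published supplementary media
# are not redistributed). Exchange ids follow the consensus r_#### scheme;
# override this file for models with other identifiers.
# Sign convention: negative lower bound = uptake allowed.
reaction_id	lower_bound	upper_bound
r_1714	-10	Inf
r_1992	-Inf	Inf
r_1654	-Inf	Inf
r_2005	-Inf	Inf
r_2060	-Inf	Inf
r_1832	-Inf	Inf
r_2100	-Inf	Inf
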