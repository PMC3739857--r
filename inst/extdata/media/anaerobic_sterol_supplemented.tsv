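# SYNTHETIC best-effort anaerobic medium supplemented with the six sterols
# whose exchange reactions must carry strictly negative (uptake) lower
# bounds for simulated anaerobic growth: episterol, ergosterol, fecosterol,
# lanosterol, zymosterol and ergosta-5,7,22,24(28)-tetraen-3beta-ol.
# The sterol exchange ids below are best guesses for the consensus network
# and could not be verified offline — OVERRIDE them against your model file
# (match the exchange reactions by metabolite name).
reaction_id	lower_bound	upper_bound
r_1714	-10	Inf
r_1992	0	Inf
r_1654	-Inf	Inf
r_2005	-Inf	Inf
r_2060	-Inf	Inf
r_1832	-Inf	Inf
r_2100	-Inf	Inf
r_1753	-1	Inf
r_1757	-1	Inf
r_1788	-1	Inf
r_1899	-1	Inf
r_2106	-1	Inf
r_1761	-1	Inf
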