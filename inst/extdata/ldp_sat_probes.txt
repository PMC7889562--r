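# Published satellite-derived FISH probe sequences, spacing as printed
LDP_SAT-H1	GCG AAA CTT GCC CGA AAT AGC AAA ATC GCC GTT TCT GGC CTA T
LDP_SAT-H2	CGA AAT AGC AAA ATC GCC GTT TCT GGC CTA TCC GGG GGC CTT TTC GG
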